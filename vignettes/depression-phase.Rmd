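---
title: "Phase leads from short-term synaptic depression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase leads from short-term synaptic depression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpphase)
```

## The question the package addresses

A postsynaptic neuron driven through depressing synapses does not simply
track a rhythmically modulated input rate: vesicle depletion at the release
sites makes synaptic efficacy *lag* the drive, and because efficacy falls
while the input rate rises, the postsynaptic response can *lead* it. The
size of that phase lead depends on how a fixed pool of release sites is
wired: one giant active zone driven by a single axon (calyx-like) behaves
as a coincidence detector and can respond almost in anti-phase, while many
single-site zones driven by independent axons (cortical-like) temporally
integrate and show a modest lead with a resonance in modulation frequency.

`stpphase` simulates this pathway end to end and, in parallel, implements
the analytical theory that predicts the phases, so each side can be checked
against the other.

## The model pipeline

**Stimulus.** Each of $M$ presynaptic neurons fires as an inhomogeneous
Poisson process with common rate
$$\lambda_S(t) = A + B\sin(2\pi f t),$$
by default $A = 30$ Hz, $B = 20$ Hz (rate swinging between 10 and 50 Hz)
and $f \in [0.1, 5]$ Hz. Trains are generated by thinning against the tight
dominating rate $A+B$, and every accepted spike imposes a 2 ms dead time.
We implement the dead time as *deletion* of candidates falling within 2 ms
of the last retained spike — the simplest reading of a thinning procedure
"modified" by refractoriness — which makes the long-run rate of an
unmodulated train $A/(1 + A\,\tau_{ref})$; the unit tests verify this
against an event-by-event renewal oracle. The modulation starts at sine
phase zero, so $\lambda_S(0) = A$ and the rate is continuous from the
start.

**Release.** $N = 512$ single-vesicle release sites are split equally
between the $M$ active zones. At a presynaptic spike of a zone, each of its
occupied sites releases independently with probability $P_v = 0.25$; a
released site refills after an exponential delay with mean
$\tau_{rec} = 0.5$ s. Rather than stepping an occupancy automaton with
refill probability $\Delta t/\tau_{rec}$, the simulator is event-driven:
each site stores its next availability time, initialised to zero (all
sites filled), and draws one exponential per release. The two schemes are
distribution-equivalent (tested by a $\chi^2$ comparison against a
small-step automaton oracle). The fraction of a zone's sites occupied just
before each spike is recorded as a diagnostic; it is the Monte-Carlo twin
of the availability ODE below.

**Postsynaptic neuron.** The dimensionless conductance follows the
difference-of-exponentials model
$$\frac{dg}{dt} = -\frac{g}{\tau_d} + x, \qquad
  \tau_{rise}\frac{dx}{dt} = -x + r(t),$$
driven by the vesicle-count process $r(t)$; $\tau_{rise} = 0$ (delta
synapse) sets $x = r$. The membrane is a single compartment, either
Hodgkin–Huxley with fast sodium ($\bar g_{Na} m^2 h$) and
delayed-rectifier potassium ($\bar g_K n^2$) currents — logistic
steady-state activations, fixed gating time constants
$\tau_m = 0.05$, $\tau_h = 0.5$, $\tau_n = 2$ ms — or leaky
integrate-and-fire with threshold $-51.5$ mV, reset $-80$ mV and a 1.8 ms
refractory clamp. Both share the passive membrane: $C_m = 1\,\mu$F cm$^{-2}$,
$g_l = 2\times10^{-4}$ S cm$^{-2}$, so $\tau = C_m/g_l = 5$ ms.
Integration is forward Euler from $v(0) = -66$ mV with zero gating, at
$t_s = 0.05$ ms for $f \le 1$ Hz and $0.05/f$ ms above. HH output spikes
are upward crossings of an absolute 10 mV threshold.

**Phase estimation.** Output spikes pooled over repeats are binned into
$t_b = 5$ ms PSTH bins after discarding the first three modulation cycles
(the simulation starts with a full vesicle pool, so the first cycles are
transient). The circular order parameter
$$\bar r e^{i\bar\phi} = \frac{1}{K}\sum_{k=1}^{K} r_k\,
  e^{i 2\pi f t_b k}$$
gives the mean response phase $\bar\phi$, and the phase lead is
$\phi_l = \pi/2 - \bar\phi$ (the input sine peaks at phase $\pi/2$),
reported in degrees wrapped to $(-180, 180]$.

## The analytical side

The probability that a site is occupied when a spike arrives obeys
$$\frac{dP_{A|S}}{dt} = \frac{1 - P_{A|S}}{\tau_{rec}}
  - P_v\,\lambda_S(t)\,P_{A|S},$$
solved with classical RK4 (the theory path is cheap, so there is no reason
to mirror the simulator's Euler scheme). Linearising the periodic forcing
gives the closed-form steady state
$$P_{A|S}(t) \approx \frac{\kappa}{\tau_{rec}}\Big(1 +
  \frac{B P_v \kappa}{\sqrt{1+\omega^2\kappa^2}}
  \cos(\omega t + \arctan(1/\omega\kappa))\Big), \qquad
  \kappa = \frac{1}{1/\tau_{rec} + P_v A},$$
whose phase relative to $\lambda_S$ is $\Theta = \pi - \arctan(\omega\kappa)$.

```{r closed-form}
p <- theory_params() # A = 30, B = 20 Hz, P_v = 0.25, tau_rec = 0.5 s
c(closed_form_deg = availability_phase(1, p) * 180 / pi,
  numeric_deg = availability_phase_numeric(p, f = 1) * 180 / pi)
```

To couple availability to output spiking across configurations, the
expected number of arrivals in a window $\tau_p$ is quantized with a
ceiling — a spike either arrives or it does not, which is what makes the
$M = 1$ pathway all-or-nothing — giving the release-rate proxy
$$c(t) = N_M P_v P_{A|S}(t)\,\lceil \tau_p M \lambda_S(t)\rceil$$
whose relative Fourier phase `theta_Mf()` reproduces the simulated trend
of phase lead with $M$ and $f$. Without the ceiling, $c(t)$ is the same
for every configuration. In the large-$M$ limit the phase of
$P_{A|S}(t)\lambda_S(t)$ reduces to
$$\hat\theta(\omega) = \arctan(\omega\tau_{rec}) - \arctan(\omega\kappa)
 - \pi/2,$$
maximised at $\omega^* = 1/\sqrt{\tau_{rec}\kappa}$:

```{r resonance}
resonance_frequency(p) # Hz
```

The recovery-time symbol inside the first arctangent is taken to be
$\tau_{rec}$: with that reading the stated maximiser is the exact argmax,
which the tests confirm numerically to six decimals. Phases of all
theoretical quantities are measured *relative to the input* by dividing
out the first Fourier coefficient of $\lambda_S$ computed on the same
grid; this removes any dependence on the transform sign convention and
makes the numeric and closed-form routes agree identically in the
no-ceiling limit.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| $A$, $B$ | 30, 20 | Hz | mean and depth of the rate modulation |
| $f$ | 0.1–5 | Hz | modulation frequency (sweep axis) |
| $N$, $M$ | 512, 1–512 | – | release-site pool and its partition |
| $P_v$ | 0.25 | – | release probability per occupied site |
| $\tau_{rec}$ | 0.5 | s | refill time constant; sets $\kappa$ and $f^*$ |
| $\tau_{rise}$, $\tau_d$ | 0.1, 1 | ms | synaptic conductance kinetics |
| $w_M$ | 0.12–0.42 | – | per-$M$ conductance calibration |
| $\tau_p$ | 30 | ms | arrival-aggregation window of the theory |
| $t_b$ | 5 | ms | PSTH bin width |

The weights $w_M$ are a calibration, not a prediction: they were chosen so
that every configuration fires at similar, low rates (about 5–25
spikes/s), which the acceptance suite asserts. The absolute scale is
$w_M \times 1.2915$ nS for $\tau_{rise} = 0.1$ ms and $w_M \times 1$ nS for
the delta synapse; $1.2915 = (\tau_{rise}/\tau_d)^{-\tau_{rise}/(\tau_d-\tau_{rise})}$
exactly compensates the peak attenuation of the double-exponential
response, so both rise-time variants deliver the same peak conductance per
vesicle. Because the finite-rise response nevertheless carries
$(\tau_d + \tau_{rise})/\tau_d \times 1.2915 \approx 1.42\times$ the charge
per vesicle, firing rates (and, mildly, phases — of order 10°) differ
between the two variants; the phase *trend* across $M$ and $f$ does not.

## Numerical choices and degenerate inputs

- **Units.** The membrane equations are integrated in mV/ms with
  capacitance in $\mu$F cm$^{-2}$ and conductances in S cm$^{-2}$ as
  tabulated; every current term is then mA cm$^{-2}$ against
  $C_m\,dv/dt$ in $\mu$A cm$^{-2}$, so the integrators carry an explicit
  factor 1000. A unit test pins the passive time constant to 5 ms, which
  fails loudly if this conversion is disturbed.
- **Synaptic sign.** The current is reported as
  $\bar g_{syn} g (v - E_{syn})$ (positive outward at $v > E_{syn}$), and
  enters $dv/dt$ as $-\bar g_{syn} g (v - E_{syn})/a$ — the standard
  depolarising conductance convention for an excitatory AMPA synapse. A
  test asserts that release events produce EPSPs.
- **Release injection.** A release at $t$ is applied at the Euler step
  containing $t$ (right-aligned); counts are conserved exactly. The delta
  synapse injects $r/\Delta t$ so the conductance jump per vesicle is
  step-size invariant.
- **Convergence.** Forward Euler at $t_s = 0.05$ ms equals $\tau_m$, so
  gating is at the edge of its stability range and halving the step
  changes most spike times by well under 0.05 ms but can shift isolated
  near-threshold crossings by a few ms, or create/remove one. This is a
  property of the printed method, not a bug; the convergence test
  therefore asserts equal spike counts, a sub-0.05 ms median shift and a
  bounded tail rather than uniform convergence. At $f = 1$ Hz a 2 ms
  timing shift is 0.7° of phase, far below the stochastic spread.
- **Ties and ordering.** Simultaneous spikes in different zones are
  processed in zone order; within a zone the dead time precludes ties.
  RNG sub-streams derive deterministically from the master seed and a
  label (neuron id, repeat index, model), so a neuron's train is invariant
  to $M$, vesicle randomness is independent of spike randomness, and every
  sweep cell is reproducible in isolation.
- **Degenerate inputs.** $P_v = 0$ yields a flagged sweep row (phase
  undefined) rather than an error; an all-uniform PSTH raises an explicit
  "phase undefined" error; recordings shorter than the discard window are
  rejected; $|v| > 200$ mV aborts with a step-size message.
- **Bin phase.** The printed order-parameter formula indexes bins by their
  right edge, which biases $\bar\phi$ by up to $\pi f t_b$ (1.8° at 1 Hz,
  comparable to the stochastic spread at desk scale); a bin-centre mode is
  provided but the printed convention is the default.

## What the generator emulates — and what it does not

The synthetic drive captures Poisson irregularity, common-rate modulation
across afferents, refractoriness and stochastic univesicular release with
exponential refill. It does *not* capture facilitation, augmentation,
calcium- or activity-dependent recovery, multivesicular release, receptor
saturation or desensitisation, dendritic filtering, correlated input noise
beyond the shared rate, or conduction delays. Passing tests therefore
demonstrate internal consistency of the depression-only model and its
theory at the stated parameters, not that a biological synapse will show
these exact phases. The refractory dead time also makes the realised drive
slightly weaker than the $\lambda_S$ used by the theory (about 6% at 30
Hz), one reason the Monte-Carlo availability is compared to the ODE with a
0.04 absolute tolerance rather than a purely statistical one.

## Scale of the shipped experiments

A full-scale study of this system would pool on the order of 100 input
sets $\times$ 100 release repeats of 23-cycle runs per cell. The package
defaults to 20 input sets $\times$ 5 release repeats — enough to estimate a pooled phase
to a few degrees at $f = 1$ Hz — and the test and acceptance suites run 12
to 20 pooled repeats of full 23-cycle simulations, which reproduce the
headline phases within their $\pm10°$ bands in well under a minute per
configuration. All repeat counts are ordinary configuration fields, so
full-scale runs need only a larger `repeats_spikes`/`repeats_release`.

## Known limitations

- The phase lead of the $M = 1$ giant pathway is reported as a lead near
  $+90°$, but functionally the response is close to anti-phase; whether to
  read near-anti-phase responses as leads or lags is a reporting decision
  left to the caller (the estimator returns both $\bar\phi$ and $\phi_l$).
- `theta_Mf()` is a one-parameter ($\tau_p$) qualitative bridge between
  theory and simulation: it reproduces trends and the resonance, with
  quantitative agreement best at large $M$ and higher $f$.
- The LIF spike time is quantised to the Euler grid, and its refractory
  clamp holds the potential at reset while conductances keep evolving.
- Event-driven release stores one availability time per site, so memory
  scales with $N$, not with activity; this is negligible here but the
  simulator is not optimised for $N \gg 10^4$.
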