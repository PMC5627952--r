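#' Synaptic conductance parameters
#'
#' The dimensionless conductance `g(t)` follows the difference-of-exponentials
#' model \deqn{dg/dt = -g/\tau_d + x, \qquad \tau_{rise}\,dx/dt = -x + r(t),}
#' where `r(t)` is the vesicle-release count process. `tau_rise = 0` is the
#' delta synapse, `x(t) = r(t)`. Absolute conductance is `g_peak * g(t)`.
#'
#' @param tau_rise rise time constant (ms; 0 or 0.1).
#' @param tau_d decay time constant (ms; default 1, the long-integration
#'   variant uses 10).
#' @param g_peak peak synaptic conductance (S), e.g. from
#'   [peak_conductance()].
#' @param E_syn synaptic reversal potential (mV; 0 for AMPA).
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(tau_rise = 0.1, tau_d = 1,
                           g_peak = peak_conductance(1, tau_rise),
                           E_syn = 0) {
  if (tau_rise < 0 || tau_rise >= tau_d)
    stop("require 0 <= tau_rise < tau_d")
  if (g_peak <= 0) stop("g_peak must be > 0")
  structure(list(tau_rise = tau_rise, tau_d = tau_d, g_peak = g_peak,
                 E_syn = E_syn),
            class = "synapse_params")
}

#' Membrane parameters for the HH and LIF neuron models
#'
#' Defaults describe a single cylindrical compartment (20 um diameter and
#' length). The HH variant uses fast sodium (`gbar_Na m^2 h`) and
#' delayed-rectifier potassium (`gbar_K n^2`) currents with logistic
#' steady-state activations and fixed time constants; the LIF variant shares
#' the passive membrane (time constant `C_m / g_l` = 5 ms).
#'
#' @param C_m membrane capacitance (uF cm^-2).
#' @param g_l leak conductance (S cm^-2).
#' @param g_K,g_Na peak channel conductances (S cm^-2, HH only).
#' @param E_l,E_K,E_Na reversal potentials (mV).
#' @param tau_m,tau_h,tau_n gating time constants (ms, HH only).
#' @param area membrane area (cm^2).
#' @param v_thresh spiking threshold (mV, LIF only).
#' @param v_reset reset potential (mV, LIF only).
#' @param t_refrac refractory time (ms, LIF only).
#' @param v0 initial membrane potential (mV).
#' @return an object of class `membrane_params`.
#' @export
membrane_params <- function(C_m = 1, g_l = 2e-4, g_K = 0.030, g_Na = 0.025,
                            E_l = -66, E_K = -95, E_Na = 50,
                            tau_m = 0.05, tau_h = 0.5, tau_n = 2,
                            area = 1.2566e-5, v_thresh = -51.5,
                            v_reset = -80, t_refrac = 1.8, v0 = -66) {
  stopifnot(C_m > 0, g_l > 0, area > 0)
  if (v_reset >= v_thresh) stop("require v_reset < v_thresh")
  structure(list(C_m = C_m, g_l = g_l, g_K = g_K, g_Na = g_Na, E_l = E_l,
                 E_K = E_K, E_Na = E_Na, tau_m = tau_m, tau_h = tau_h,
                 tau_n = tau_n, area = area, v_thresh = v_thresh,
                 v_reset = v_reset, t_refrac = t_refrac, v0 = v0),
            class = "membrane_params")
}

#' Integration time step as a function of modulation frequency
#'
#' 0.05 ms for `f <= 1` Hz and `0.05 / f` ms above, so that one modulation
#' cycle is always resolved by the same number of Euler steps (the two rules
#' coincide at `f = 1`).
#'
#' @param f modulation frequency (Hz).
#' @return time step in ms.
#' @export
#' @examples
#' timestep_for(c(0.1, 1, 5))
timestep_for <- function(f) {
  if (any(f <= 0)) stop("f must be > 0")
  ifelse(f <= 1, 0.05, 0.05 / f)
}

# Calibrated per-M conductance weights.
.w_table <- c(`1` = 0.12, `2` = 0.17, `4` = 0.23, `8` = 0.29, `16` = 0.32,
              `32` = 0.35, `64` = 0.38, `128` = 0.4, `256` = 0.41,
              `512` = 0.42)

#' Calibrated peak synaptic conductance per synaptic configuration
#'
#' Returns `w_M * scale`, where `w_M` is the calibrated weight for the given
#' number of active zones (chosen so that mean postsynaptic rates stay in a
#' 5-25 spikes/s band across configurations) and `scale` is 1.2915e-9 S for
#' `tau_rise = 0.1` ms or 1e-9 S for the delta synapse. The 1.2915 factor is
#' exactly `1 / (tau_rise/tau_d)^(tau_rise/(tau_d - tau_rise))` at
#' `tau_rise = 0.1`, `tau_d = 1` ms, i.e. it normalises the peak of the
#' double-exponential impulse response so both rise-time variants produce
#' the same peak conductance per vesicle.
#'
#' @param M number of active zones; must be one of 1, 2, 4, ..., 512 unless
#'   a custom weight `w` is supplied.
#' @param tau_rise rise time constant (ms).
#' @param w optional custom weight overriding the calibration table.
#' @return peak conductance in S.
#' @export
#' @examples
#' peak_conductance(1)
#' peak_conductance(512, tau_rise = 0)
peak_conductance <- function(M, tau_rise = 0.1, w = NULL) {
  if (is.null(w)) {
    key <- as.character(M)
    if (!key %in% names(.w_table))
      stop(sprintf("no calibrated weight for M = %s; supply w explicitly", key))
    w <- .w_table[[key]]
  }
  scale <- if (tau_rise > 0) 1.2915e-9 else 1e-9
  w * scale
}

#' Net synaptic current
#'
#' `I = g_peak * g * (v - E_syn)`, returned in amperes. This is the printed
#' form of the current; inside the integrators its contribution to `dv/dt`
#' is applied with the depolarising conductance convention
#' `-g_peak * g * (v - E_syn) / area`, so that release events drive the
#' membrane toward `E_syn` (EPSPs).
#'
#' @param g dimensionless conductance value(s).
#' @param v membrane potential (mV).
#' @param syn a [synapse_params()] object.
#' @return current in A (vectorised).
#' @export
#' @examples
#' synaptic_current(1, -66, synapse_params(g_peak = 1e-9)) # -66 pA
synaptic_current <- function(g, v, syn) {
  syn$g_peak * g * (v - syn$E_syn) * 1e-3 # S * mV = mA -> A
}

# Right-aligned binning of release events onto the Euler grid: a release in
# ((i-1)*dt, i*dt] is injected at step i. Counts are conserved (events past
# the grid end are dropped with a warning).
#' Bin release counts onto the integration grid
#'
#' @param times_s release event times (s).
#' @param counts vesicles released at each event.
#' @param dt time step (ms).
#' @param n_steps number of steps.
#' @return integer vector of per-step release counts, length `n_steps`.
#' @export
bin_release_counts <- function(times_s, counts, dt, n_steps) {
  if (length(times_s) == 0) return(integer(n_steps))
  idx <- ceiling(times_s * 1000 / dt)
  idx[idx < 1] <- 1L
  drop <- idx > n_steps
  if (any(counts[drop] > 0))
    warning("release events beyond the integration window were dropped")
  idx <- idx[!drop]
  counts <- counts[!drop]
  out <- numeric(n_steps)
  tab <- tapply(counts, idx, sum)
  out[as.integer(names(tab))] <- tab
  out
}

.as_release_events <- function(release) {
  if (inherits(release, "release_train")) release$events else release
}

#' Integrate the postsynaptic membrane (HH or LIF) by forward Euler
#'
#' `run_hh()` solves the four coupled HH equations (voltage plus `m`, `h`,
#' `n` gating) from `v(0) = -66` mV and zero gating; output spikes are the
#' upward crossings of 10 mV. `run_lif()` solves the passive equation with
#' threshold `v_thresh`, reset `v_reset` and refractory clamp `t_refrac`.
#' Release counts are injected into the conductance at the Euler step
#' containing each event.
#'
#' @param release a `release_train` (all zones feed the one neuron) or a
#'   data.frame with columns `time` (s) and `count`.
#' @param syn a [synapse_params()] object.
#' @param mem a [membrane_params()] object.
#' @param f modulation frequency (Hz), used to choose the default step via
#'   [timestep_for()].
#' @param duration total integration time (s).
#' @param dt Euler step (ms).
#' @param keep_trace if `TRUE`, store the full state trajectories (memory
#'   ~ 8 bytes x steps x 5 variables).
#' @return an object of class `neuron_trace`: `spike_times` (s), `model`,
#'   `dt` (ms), `duration` (s) and, if requested, `time` (s), `v`, `g` (and
#'   `m`, `h`, `n` for HH).
#' @export
run_hh <- function(release, syn, mem, f = 1, duration,
                   dt = timestep_for(f), keep_trace = FALSE) {
  ev <- .as_release_events(release)
  n_steps <- round(duration * 1000 / dt)
  r <- bin_release_counts(ev$time, ev$count, dt, n_steps)
  res <- hh_sim_cpp(r, dt, syn$g_peak, syn$E_syn, syn$tau_rise, syn$tau_d,
                    mem$C_m, mem$g_l, mem$g_K, mem$g_Na, mem$E_l, mem$E_K,
                    mem$E_Na, mem$tau_m, mem$tau_h, mem$tau_n, mem$area,
                    mem$v0, keep_trace)
  out <- list(model = "hh", spike_times = res$spike_times, dt = dt,
              duration = duration)
  if (keep_trace) {
    out$time <- seq(0, n_steps) * dt / 1000
    out[c("v", "m", "h", "n", "g")] <- res[c("v", "m", "h", "n", "g")]
  }
  structure(out, class = "neuron_trace")
}

#' @rdname run_hh
#' @export
run_lif <- function(release, syn, mem, f = 1, duration,
                    dt = timestep_for(f), keep_trace = FALSE) {
  ev <- .as_release_events(release)
  n_steps <- round(duration * 1000 / dt)
  r <- bin_release_counts(ev$time, ev$count, dt, n_steps)
  res <- lif_sim_cpp(r, dt, syn$g_peak, syn$E_syn, syn$tau_rise, syn$tau_d,
                     mem$C_m, mem$g_l, mem$E_l, mem$area, mem$v_thresh,
                     mem$v_reset, mem$t_refrac, mem$v0, keep_trace)
  out <- list(model = "lif", spike_times = res$spike_times, dt = dt,
              duration = duration)
  if (keep_trace) {
    out$time <- seq(0, n_steps) * dt / 1000
    out[c("v", "g")] <- res[c("v", "g")]
  }
  structure(out, class = "neuron_trace")
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat(sprintf("%s trace: %.3g s at dt = %g ms, %d spikes (%.1f Hz)\n",
              toupper(x$model), x$duration, x$dt, length(x$spike_times),
              length(x$spike_times) / x$duration))
  invisible(x)
}

#' Detect output spikes from a membrane-potential trace
#'
#' For the HH model a spike is an upward crossing of the absolute 10 mV
#' threshold (`v(t - dt) < 10` and `v(t) > 10`); for a LIF trace the spike
#' times recorded during integration are returned (crossings of `v_thresh`).
#'
#' @param trace a `neuron_trace` with a stored voltage trajectory, or any
#'   list with elements `time` (s) and `v` (mV).
#' @param threshold detection threshold (mV) for voltage traces.
#' @return spike times in seconds.
#' @export
detect_spikes <- function(trace, threshold = 10) {
  if (inherits(trace, "neuron_trace") && identical(trace$model, "lif"))
    return(trace$spike_times)
  if (is.null(trace$v))
    stop("trace has no stored voltage; rerun with keep_trace = TRUE")
  v <- trace$v
  up <- which(v[-length(v)] < threshold & v[-1] > threshold)
  trace$time[up + 1]
}
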