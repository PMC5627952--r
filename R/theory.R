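#' Parameters of the analytical depression-phase model
#'
#' Bundles the stimulus (`A`, `B`) and depression (`P_v`, `tau_rec`)
#' parameters and derives the effective depression time constant
#' \deqn{\kappa = 1 / (1/\tau_{rec} + P_v A),} the time constant with which
#' vesicle availability relaxes under the mean drive. `tau_p` is the
#' spike-aggregation window of the quantized release-rate estimator.
#'
#' @param A mean input rate (Hz).
#' @param B peak modulation (Hz).
#' @param P_v release probability.
#' @param tau_rec replenishment time constant (s).
#' @param tau_p spike-aggregation window (s, default 0.03).
#' @return an object of class `theory_params` with derived field `kappa`.
#' @export
#' @examples
#' theory_params()$kappa # 1/9.5
theory_params <- function(A = 30, B = 20, P_v = 0.25, tau_rec = 0.5,
                          tau_p = 0.03) {
  stopifnot(A > 0, B >= 0, A - B > 0, P_v >= 0, P_v <= 1, tau_rec > 0,
            tau_p > 0)
  kappa <- 1 / (1 / tau_rec + P_v * A)
  structure(list(A = A, B = B, P_v = P_v, tau_rec = tau_rec, tau_p = tau_p,
                 kappa = kappa),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf(
    "Depression theory: A=%g, B=%g Hz, P_v=%g, tau_rec=%g s -> kappa=%.4g s; tau_p=%g s\n",
    x$A, x$B, x$P_v, x$tau_rec, x$kappa, x$tau_p))
  invisible(x)
}

.lambda_s <- function(t, p, f) p$A + p$B * sin(2 * pi * f * t)

#' Numerically solve the vesicle-availability ODE
#'
#' The conditional probability that a release site holds a vesicle at spike
#' arrival, \eqn{P_{A|S}(t)}, obeys
#' \deqn{dP/dt = (1 - P)/\tau_{rec} - P_v\,\lambda_S(t)\,P,}
#' solved here with classical RK4 from `P(0) = 1` (all sites filled). The
#' transient decays on the scale of `kappa`.
#'
#' @param p a [theory_params()] object.
#' @param f modulation frequency (Hz).
#' @param n_cycles number of cycles to integrate (default 10).
#' @param dt solver step (s); defaults to a step resolving both `kappa` and
#'   the modulation period.
#' @return an object of class `availability_trace`: data.frame fields
#'   `time`, `P`, plus `f` and the parameters.
#' @export
#' @examples
#' tr <- solve_availability_ode(theory_params(B = 0), f = 1, n_cycles = 5)
#' tail(tr$P, 1) # -> 1/4.75
solve_availability_ode <- function(p, f = 1, n_cycles = 10, dt = NULL) {
  stopifnot(inherits(p, "theory_params"), f > 0, n_cycles >= 1)
  if (is.null(dt)) dt <- min(p$kappa, 1 / f) / 1000
  times <- seq(0, n_cycles / f, by = dt)
  deriv <- function(t, y, parms)
    list((1 - y) / p$tau_rec - p$P_v * .lambda_s(t, p, f) * y)
  sol <- deSolve::ode(y = c(P = 1), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  structure(list(time = sol[, 1], P = sol[, 2], f = f, params = p, dt = dt),
            class = "availability_trace")
}

# Relative phase (radians in [0, 2*pi)) of x(t) with respect to the input
# sinusoid at frequency f, via first Fourier coefficients on a common grid.
.fourier_phase <- function(t, x, p, f) {
  zx <- sum(x * exp(-1i * 2 * pi * f * t))
  zl <- sum(.lambda_s(t, p, f) * exp(-1i * 2 * pi * f * t))
  wrap_2pi(Arg(zx / zl))
}

#' Phase of the numerically solved availability relative to the input
#'
#' Integrates the availability ODE, discards the transient and extracts the
#' phase of the fundamental Fourier component of \eqn{P_{A|S}(t)} relative
#' to \eqn{\lambda_S(t)} on the same grid.
#'
#' @inheritParams solve_availability_ode
#' @param discard_cycles whole cycles dropped before phase extraction.
#' @return phase shift in radians, `[0, 2*pi)`.
#' @export
#' @examples
#' availability_phase_numeric(theory_params(), f = 1) * 180 / pi # 144.54
availability_phase_numeric <- function(p, f = 1, n_cycles = 10, dt = NULL,
                                       discard_cycles = 5) {
  stopifnot(n_cycles > discard_cycles)
  tr <- solve_availability_ode(p, f = f, n_cycles = n_cycles, dt = dt)
  keep <- tr$time >= discard_cycles / f & tr$time < n_cycles / f
  .fourier_phase(tr$time[keep], tr$P[keep], p, f)
}

#' Closed-form approximate availability
#'
#' First-order approximation of the steady-state availability,
#' \deqn{P_{A|S}(t) \approx \frac{\kappa}{\tau_{rec}}\left(1 +
#' \frac{B P_v \kappa}{\sqrt{1+\omega^2\kappa^2}}
#' \cos(\omega t + \arctan(1/(\omega\kappa)))\right).}
#'
#' @param t time(s) in seconds.
#' @param p a [theory_params()] object.
#' @param f modulation frequency (Hz).
#' @return approximate availability values.
#' @export
availability_approx <- function(t, p, f = 1) {
  w <- 2 * pi * f
  k <- p$kappa
  amp <- p$B * p$P_v * k / sqrt(1 + w^2 * k^2)
  (k / p$tau_rec) * (1 + amp * cos(w * t + atan(1 / (w * k))))
}

#' Closed-form availability phase
#'
#' The phase shift of the availability relative to the input modulation,
#' \deqn{\Theta = \pi - \arctan(\omega\kappa)
#'             = \pi - \arctan\!\left(\frac{\tau_{rec}\,\omega}
#'               {1 + \tau_{rec} P_v A}\right),}
#' which approaches \eqn{\pi} as `f -> 0`.
#'
#' @param f modulation frequency (Hz), vectorised.
#' @param p a [theory_params()] object.
#' @return phase shift in radians.
#' @export
#' @examples
#' availability_phase(1, theory_params()) * 180 / pi # 146.52
availability_phase <- function(f, p) {
  pi - atan(2 * pi * f * p$kappa)
}

#' Expected and quantized presynaptic arrivals in an aggregation window
#'
#' `expected_arrivals()` is the expected number of spikes arriving across
#' all `M` presynaptic neurons in a window `tau_p`, approximated as
#' `M * tau_p * lambda_S(t)`; `quantized_arrivals()` applies the ceiling
#' operator to model the all-or-nothing arrival of whole spikes (crucial
#' when `M` is small).
#'
#' @param t time(s) in seconds.
#' @param M number of active zones.
#' @param p a [theory_params()] object.
#' @param f modulation frequency (Hz).
#' @param tau_p aggregation window (s); defaults to `p$tau_p`.
#' @return arrival counts (expected: real; quantized: integer-valued).
#' @export
expected_arrivals <- function(t, M, p, f = 1, tau_p = p$tau_p) {
  if (tau_p * f >= 0.5)
    warning("tau_p is not small compared to the modulation period")
  M * tau_p * .lambda_s(t, p, f)
}

#' @rdname expected_arrivals
#' @export
quantized_arrivals <- function(t, M, p, f = 1, tau_p = p$tau_p) {
  ceiling(expected_arrivals(t, M, p, f = f, tau_p = tau_p))
}

#' Quantized release-rate proxy for the postsynaptic drive
#'
#' \deqn{c(t) = N_M P_v P_{A|S}(t) \lceil \tau_p M \lambda_S(t)\rceil,}
#' with `N_M = N / M`. Without the ceiling, `c(t)` is identical for every
#' configuration; the quantization is what makes small-`M` pathways behave
#' as coincidence detectors.
#'
#' @inheritParams expected_arrivals
#' @param N total release sites (default 512).
#' @return proxy release rate values.
#' @export
release_rate_proxy <- function(t, M, p, f = 1, tau_p = p$tau_p, N = 512) {
  (N / M) * p$P_v * availability_approx(t, p, f = f) *
    quantized_arrivals(t, M, p, f = f, tau_p = tau_p)
}

#' Theoretical phase surface over configuration and frequency
#'
#' Phase of the quantized release-rate proxy relative to the input
#' modulation, \deqn{\Theta(M, f) = \arg\!\int_0^{1/f} P_{A|S}(t)
#' \lceil\tau_p M \lambda_S(t)\rceil e^{-i 2\pi f t}\,dt \Big/ z_\lambda,}
#' where dividing by the input's own Fourier coefficient \eqn{z_\lambda}
#' fixes the phase reference so that in the availability-dominated limit
#' this reduces to [availability_phase()].
#'
#' @param M number of active zones (vectorised).
#' @param f modulation frequency (Hz, vectorised; recycled against `M`).
#' @param p a [theory_params()] object.
#' @param tau_p aggregation window (s).
#' @param availability `"approx"` uses the closed-form availability;
#'   `"numeric"` the RK4 ODE solution.
#' @param dt integration grid step (s); must resolve the ceiling steps
#'   (default `tau_p / 20`).
#' @return phase shift(s) in radians, `[0, 2*pi)`.
#' @export
#' @examples
#' theta_Mf(c(1, 512), 1, theory_params()) * 180 / pi
theta_Mf <- function(M, f, p, tau_p = p$tau_p,
                     availability = c("approx", "numeric"), dt = tau_p / 20) {
  availability <- match.arg(availability)
  n <- max(length(M), length(f))
  M <- rep_len(M, n)
  f <- rep_len(f, n)
  vapply(seq_len(n), function(i) {
    tt <- seq(0, 1 / f[i], by = min(dt, 1 / (f[i] * 400)))
    tt <- tt[-length(tt)]
    P <- if (availability == "approx") {
      availability_approx(tt, p, f = f[i])
    } else {
      tr <- solve_availability_ode(p, f = f[i], n_cycles = 8)
      keep <- tr$time >= 7 / f[i] & tr$time < 8 / f[i]
      stats::approx(tr$time[keep] - 7 / f[i], tr$P[keep], xout = tt,
                    rule = 2)$y
    }
    cc <- P * quantized_arrivals(tt, M[i], p, f = f[i], tau_p = tau_p)
    .fourier_phase(tt, cc, p, f[i])
  }, numeric(1))
}

#' Large-M phase approximation and its resonance
#'
#' For the cortical limit (ceiling dropped) the phase of
#' \eqn{\hat c(t) = P_{A|S}(t)\lambda_S(t)} reduces to
#' \deqn{\hat\theta(\omega) = \arctan(\omega\tau_{rec}) -
#' \arctan(\omega\kappa) - \pi/2,} maximised at
#' \eqn{\omega^* = 1/\sqrt{\tau_{rec}\,\kappa}}, giving the resonance
#' frequency \eqn{f^* = \omega^*/(2\pi)} of the phase lead. `B` does not
#' enter, so the resonance is independent of modulation depth.
#'
#' @param omega angular frequency(ies), rad/s.
#' @param p a [theory_params()] object.
#' @return `theta_hat()`: phase in radians; `resonance_frequency()`: `f*`
#'   in Hz.
#' @export
#' @examples
#' resonance_frequency(theory_params()) # ~0.69
theta_hat <- function(omega, p) {
  atan(omega * p$tau_rec) - atan(omega * p$kappa) - pi / 2
}

#' @rdname theta_hat
#' @export
resonance_frequency <- function(p) {
  1 / (2 * pi * sqrt(p$tau_rec * p$kappa))
}
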