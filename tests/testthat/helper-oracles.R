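# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or via general-purpose solvers, never through the
# package's own fast paths.

# Event-by-event generation of a homogeneous Poisson train with dead-time
# deletion: candidates arrive at rate A; a candidate closer than `refractory`
# to the last retained spike is discarded.
oracle_refractory_train <- function(A, refractory, duration) {
  n_guess <- ceiling(1.3 * A * duration + 100)
  cand <- cumsum(stats::rexp(n_guess, A))
  cand <- cand[cand <= duration]
  out <- numeric(length(cand))
  last <- -Inf
  n <- 0L
  for (t in cand) {
    if (t - last >= refractory) {
      n <- n + 1L
      out[n] <- t
      last <- t
    }
  }
  out[seq_len(n)]
}

# Small-time-step stochastic automaton for vesicle occupancy: an empty site
# refills with probability dt/tau_rec per step; at each presynaptic spike
# every occupied site releases with probability p_v. Returns the total number
# of vesicles released per repeat (vectorised over repeats).
oracle_automaton_release <- function(spikes, n_sites, p_v, tau_rec, dt,
                                     n_rep) {
  n_steps <- ceiling(max(spikes) / dt) + 1L
  spike_step <- round(spikes / dt)
  occ <- matrix(TRUE, n_rep, n_sites)
  counts <- integer(n_rep)
  p_fill <- dt / tau_rec
  for (s in seq_len(n_steps)) {
    refill <- (!occ) & (matrix(stats::runif(n_rep * n_sites), n_rep) < p_fill)
    occ <- occ | refill
    if (s %in% spike_step) {
      rel <- occ & (matrix(stats::runif(n_rep * n_sites), n_rep) < p_v)
      counts <- counts + rowSums(rel)
      occ <- occ & !rel
    }
  }
  counts
}

# Phase of the fundamental Fourier component of an un-binned spike train.
oracle_spike_phase <- function(times, f) {
  Arg(sum(exp(1i * 2 * pi * f * times))) %% (2 * pi)
}

# High-accuracy reference integration of the HH equations (no synaptic
# input) with an adaptive general-purpose solver.
oracle_hh_rest <- function(mem, t_end = 200) {
  deriv <- function(t, y, p) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    mss <- 1 / (1 + exp(-(v + 40) / 3))
    hss <- 1 / (1 + exp((v + 45) / 3))
    dv <- 1000 / mem$C_m *
      (-mem$g_l * (v - mem$E_l) - mem$g_K * n^2 * (v - mem$E_K) -
         mem$g_Na * m^2 * h * (v - mem$E_Na))
    list(c(dv, (mss - m) / mem$tau_m, (hss - h) / mem$tau_h,
           (mss - n) / mem$tau_n))
  }
  sol <- deSolve::ode(c(v = -66, m = 0, h = 0, n = 0),
                      times = c(0, t_end), deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  sol[nrow(sol), "v"]
}

# Reduced-scale experiment configuration shared by the heavier end-to-end
# tests (12 pooled repeats, full 23-cycle runs).
small_cfg <- function(seed = 11, ...) {
  experiment_config(repeats_spikes = 6, repeats_release = 2, seed = seed, ...)
}
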