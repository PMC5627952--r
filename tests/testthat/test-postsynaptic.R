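# A single release of one vesicle at t0, integrated with a negligible
# coupling so the conductance trace is the pure synaptic kinetics.
impulse_trace <- function(tau_rise, tau_d = 1, dt = 0.005, dur = 0.02,
                          t0 = 0.001) {
  syn <- synapse_params(tau_rise = tau_rise, tau_d = tau_d, g_peak = 1e-18)
  rel <- data.frame(time = t0, count = 1)
  run_lif(rel, syn, membrane_params(), duration = dur, dt = dt,
          keep_trace = TRUE)
}

test_that("integration step tracks the modulation frequency", {
  expect_equal(timestep_for(0.1), 0.05)
  expect_equal(timestep_for(1), 0.05)
  expect_equal(timestep_for(5), 0.01)
  expect_error(timestep_for(0), "f")
})

test_that("calibrated peak conductances follow the weight table", {
  expect_equal(peak_conductance(1), 0.12 * 1.2915e-9)
  expect_equal(peak_conductance(512), 0.42 * 1.2915e-9)
  expect_equal(peak_conductance(512, tau_rise = 0), 0.42e-9)
  w <- sapply(2^(0:9), peak_conductance)
  expect_true(all(diff(w) > 0))
  expect_error(peak_conductance(3), "calibrated")
  expect_equal(peak_conductance(3, w = 0.2), 0.2 * 1.2915e-9)
})

test_that("conductance impulse response matches the closed-form double exponential", {
  tr <- impulse_trace(tau_rise = 0.1, dt = 0.002)
  tms <- tr$time * 1000 - 1 # ms since the release
  sel <- tms > 0
  exact <- (1 / 0.9) * (exp(-tms[sel] / 1) - exp(-tms[sel] / 0.1))
  expect_lt(max(abs(tr$g[sel] - exact)), 0.02) # Euler error at dt = 2 us
  # peak location: (tau_d*tau_rise/(tau_d - tau_rise)) * log(tau_d/tau_rise)
  t_peak <- (1 * 0.1 / 0.9) * log(10)
  expect_lt(abs(tms[sel][which.max(tr$g[sel])] - t_peak), 0.02)
  # peak amplitude is (tau_rise/tau_d)^(tau_rise/(tau_d-tau_rise)) = 1/1.2915
  expect_equal(max(tr$g), 10^(-1 / 9), tolerance = 0.01)
})

test_that("delta synapse decays purely exponentially and is the rise-time limit", {
  tr0 <- impulse_trace(tau_rise = 0, dt = 0.001)
  tms <- tr0$time * 1000 - 1
  sel <- tms > 0
  expect_lt(max(abs(tr0$g[sel] - exp(-tms[sel] / 1) * max(tr0$g))), 0.01)
  expect_equal(max(tr0$g), 1, tolerance = 0.01) # unit jump per vesicle
  # tau_rise -> 0+ converges to the delta response away from the kink
  tr_eps <- impulse_trace(tau_rise = 0.01, dt = 0.001)
  late <- tms > 0.05
  expect_lt(max(abs(tr_eps$g[late] - tr0$g[late])), 0.05)
})

test_that("synaptic current follows the printed form and depolarises the cell", {
  syn <- synapse_params(g_peak = 1e-9)
  expect_equal(synaptic_current(1, 0, syn), 0) # reversal
  expect_equal(synaptic_current(0, -66, syn), 0)
  expect_equal(abs(synaptic_current(1, -66, syn)), 66e-12) # 66 pA
  # a release event must produce an EPSP (depolarisation toward E_syn)
  rel <- data.frame(time = 0.005, count = 100)
  tr <- run_lif(rel, synapse_params(g_peak = 1e-10), membrane_params(),
                duration = 0.05, dt = 0.05, keep_trace = TRUE)
  expect_gt(max(tr$v), -66)
  expect_lt(max(tr$v), 0) # but bounded by the reversal potential
})

test_that("HH neuron at rest matches a high-accuracy reference integration", {
  mem <- membrane_params()
  ref_v <- oracle_hh_rest(mem)
  none <- data.frame(time = numeric(0), count = numeric(0))
  tr <- run_hh(none, synapse_params(g_peak = 1e-15), mem, duration = 0.3,
               dt = 0.05, keep_trace = TRUE)
  expect_length(tr$spike_times, 0)
  expect_lt(abs(tail(tr$v, 1) - ref_v), 0.05)
  late <- tr$time > 0.05 # past the gating start-up transient
  for (gv in list(tr$m, tr$h, tr$n))
    expect_true(all(gv[late] >= 0 & gv[late] <= 1))
})

test_that("suprathreshold drive produces repetitive spikes detected once per upstroke", {
  mem <- membrane_params()
  drive <- data.frame(time = seq(0.001, 0.5, by = 0.001), count = 3)
  tr <- run_hh(drive, synapse_params(g_peak = 5e-10), mem, duration = 0.5,
               dt = 0.05, keep_trace = TRUE)
  expect_gt(length(tr$spike_times), 5)
  # R-side crossing detection agrees exactly with the integrator's record
  expect_equal(detect_spikes(tr), tr$spike_times)
  # brief positive excursions below 10 mV are not spikes
  synth <- list(time = seq(0, 0.01, by = 1e-4),
                v = c(rep(-60, 50), rep(5, 51)))
  expect_length(detect_spikes(synth), 0)
  synth2 <- list(time = seq_len(8) / 1000,
                 v = c(-60, 20, -60, 5, -60, 30, -60, -60))
  expect_length(detect_spikes(synth2), 2)
})

test_that("LIF relaxes to the leak reversal with a 5 ms time constant", {
  mem <- membrane_params(v0 = -80)
  none <- data.frame(time = numeric(0), count = numeric(0))
  tr <- run_lif(none, synapse_params(g_peak = 1e-15), mem, duration = 0.03,
                dt = 0.01, keep_trace = TRUE)
  expect_length(tr$spike_times, 0)
  exact <- -66 + (-80 + 66) * exp(-tr$time * 1000 / 5)
  expect_lt(max(abs(tr$v - exact)), 0.05)
})

test_that("LIF firing under constant conductance matches the renewal closed form", {
  mem <- membrane_params()
  syn <- synapse_params(tau_rise = 0, tau_d = 1e6, g_peak = 1.5e-9)
  kick <- data.frame(time = 1e-5, count = 1) # g ~ 1 thereafter
  tr <- run_lif(kick, syn, mem, duration = 2, dt = 0.01)
  g_s <- syn$g_peak / mem$area # S cm^-2
  g_tot <- mem$g_l + g_s
  v_ss <- (mem$g_l * mem$E_l + g_s * syn$E_syn) / g_tot
  tau_eff <- mem$C_m / (1000 * g_tot) # ms
  period <- mem$t_refrac +
    tau_eff * log((v_ss - mem$v_reset) / (v_ss - mem$v_thresh))
  rate <- 1000 / period
  expect_gt(v_ss, mem$v_thresh)
  expect_equal(length(tr$spike_times) / 2, rate, tolerance = 0.02)
  # subthreshold constant conductance: no spikes at all
  syn2 <- synapse_params(tau_rise = 0, tau_d = 1e6, g_peak = 5e-10)
  tr2 <- run_lif(kick, syn2, mem, duration = 2, dt = 0.01)
  expect_length(tr2$spike_times, 0)
})

test_that("spike times converge as the Euler step is refined", {
  mem <- membrane_params()
  pop <- generate_population(4, stimulus_params(duration = 3), seed = 2)
  rel <- simulate_release(pop, synaptic_config(M = 4), seed = 102)
  syn <- synapse_params(g_peak = peak_conductance(4))
  a <- run_hh(rel, syn, mem, duration = 3, dt = 0.05)
  b <- run_hh(rel, syn, mem, duration = 3, dt = 0.025)
  expect_equal(length(a$spike_times), length(b$spike_times))
  d <- abs(a$spike_times - b$spike_times) * 1000
  expect_lt(stats::median(d), 0.05)
  expect_lt(max(d), 0.5) # isolated near-threshold crossings move most
})

test_that("release binning conserves vesicle counts", {
  r <- bin_release_counts(c(0.0004, 0.0006, 0.02), c(2, 3, 1), 0.5, 40)
  expect_equal(sum(r), 6)
  expect_equal(r[1], 2) # t = 0.4 ms lands in the first 0.5 ms step
  expect_equal(r[2], 3)
  expect_equal(r[40], 1)
  expect_warning(bin_release_counts(c(0.01, 1), c(1, 1), 0.5, 40), "dropped")
  set.seed(1)
  tt <- sort(runif(500, 0, 1))
  cc <- rpois(500, 3)
  expect_equal(sum(bin_release_counts(tt, cc, 0.05, 20000)), sum(cc))
})
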