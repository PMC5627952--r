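deg <- function(x) x * 180 / pi

test_that("availability ODE has the expected fixed points and limits", {
  p0 <- theory_params(B = 0)
  tr <- solve_availability_ode(p0, f = 1, n_cycles = 5)
  expect_equal(tail(tr$P, 1), 1 / 4.75, tolerance = 1e-5)
  expect_equal(p0$kappa / p0$tau_rec, 1 / 4.75, tolerance = 1e-12)
  pv0 <- theory_params(P_v = 0)
  tr0 <- solve_availability_ode(pv0, f = 1, n_cycles = 2)
  expect_true(all(abs(tr0$P - 1) < 1e-10))
  expect_true(all(tr$P >= 0 & tr$P <= 1))
})

test_that("closed-form availability phase matches its printed values and limits", {
  p <- theory_params()
  expect_equal(deg(availability_phase(1, p)), 146.52, tolerance = 1e-4)
  expect_equal(deg(availability_phase(5, p)), 106.83, tolerance = 1e-2)
  expect_equal(availability_phase(1e-9, p), pi, tolerance = 1e-6)
  f <- c(0.1, 0.5, 1, 2, 5)
  expect_true(all(diff(availability_phase(f, p)) < 0))
})

test_that("approximate availability carries the closed-form phase and mean", {
  p <- theory_params()
  tt <- seq(0, 1, by = 1e-4)[-10001]
  av <- availability_approx(tt, p, f = 1)
  expect_equal(mean(av), p$kappa / p$tau_rec, tolerance = 1e-6)
  # Fourier phase of the approximation equals pi - arctan(omega*kappa)
  zl <- sum((30 + 20 * sin(2 * pi * tt)) * exp(-1i * 2 * pi * tt))
  za <- sum(av * exp(-1i * 2 * pi * tt))
  expect_equal(Arg(za / zl) %% (2 * pi), availability_phase(1, p),
               tolerance = 1e-6)
  # modulation term vanishes at high frequency
  av_hi <- availability_approx(tt, p, f = 1e6)
  expect_lt(diff(range(av_hi)), 1e-4)
})

test_that("numerical and approximate availability phases agree within 2 degrees", {
  p <- theory_params()
  th_num <- deg(availability_phase_numeric(p, f = 1))
  th_cf <- deg(availability_phase(1, p))
  expect_lt(abs(th_num - th_cf), 2)
})

test_that("Monte-Carlo availability at spikes tracks the ODE solution", {
  # availability at successive spikes of one site decorrelates only over
  # tau_rec, so many independent zones and release repeats are pooled
  p <- theory_params()
  stim <- stimulus_params(duration = 10)
  pop <- generate_population(256, stim, seed = 60)
  av <- do.call(rbind, lapply(1:3, function(s) {
    rel <- simulate_release(pop, synaptic_config(N = 256, M = 256),
                            seed = 60 + s)
    a <- availability_at_spikes(rel)
    a[a$time >= 3, ]
  }))
  mc <- tapply(av$avail, ceiling((av$time %% 1) * 10), mean)
  tr <- solve_availability_ode(p, f = 1, n_cycles = 10)
  keep <- tr$time >= 9
  centres <- (as.numeric(names(mc)) - 0.5) / 10
  ode_vals <- stats::approx(tr$time[keep] - 9, tr$P[keep], xout = centres,
                            rule = 2)$y
  expect_gt(stats::cor(as.numeric(mc), ode_vals), 0.98)
  expect_lt(max(abs(as.numeric(mc) - ode_vals)), 0.04)
})

test_that("arrival quantization behaves as specified", {
  p <- theory_params(tau_p = 0.02)
  expect_equal(expected_arrivals(0.25, 1, p, f = 1), 1.0) # lambda = 50 Hz
  expect_equal(quantized_arrivals(0.25, 1, p, f = 1), 1)
  p30 <- theory_params(tau_p = 0.03)
  expect_equal(expected_arrivals(0, 512, p30, f = 1), 460.8)
  expect_equal(quantized_arrivals(0, 512, p30, f = 1), 461)
  tt <- seq(0, 1, by = 1e-3)
  for (M in c(1, 8, 512))
    expect_true(all(quantized_arrivals(tt, M, p30, f = 1) >= 1))
  expect_warning(expected_arrivals(0, 1, p30, f = 20), "tau_p")
})

test_that("without quantization the release-rate proxy is configuration-invariant", {
  p <- theory_params()
  tt <- seq(0, 1, by = 1e-3)
  smooth <- function(M) (512 / M) * p$P_v * availability_approx(tt, p, 1) *
    expected_arrivals(tt, M, p, f = 1)
  expect_equal(smooth(1), smooth(512), tolerance = 1e-12)
  expect_equal(smooth(8), smooth(64), tolerance = 1e-12)
  expect_true(all(release_rate_proxy(tt, 4, theory_params(P_v = 0), f = 1) == 0))
})

test_that("theoretical phase surface falls with M and approaches the product form", {
  p <- theory_params()
  th <- deg(theta_Mf(2^(0:9), 1, p))
  expect_true(all(diff(th) < 0.5)) # non-increasing trend across the sweep
  expect_gt(th[1], 70)  # giant-synapse end
  expect_lt(th[10], 42) # cortical end
  # ceiling becomes the identity for very large M: phase of P_A|S * lambda_S
  tt <- seq(0, 1, by = 1e-4)[-10001]
  chat <- availability_approx(tt, p, 1) * (30 + 20 * sin(2 * pi * tt))
  zl <- sum((30 + 20 * sin(2 * pi * tt)) * exp(-1i * 2 * pi * tt))
  th_chat <- deg(Arg(sum(chat * exp(-1i * 2 * pi * tt)) / zl) %% (2 * pi))
  th_big <- deg(theta_Mf(1e5, 1, p, tau_p = 0.001))
  expect_lt(abs(th_big - th_chat), 1)
  # the numeric-availability route agrees with the approximate route
  th_num <- deg(theta_Mf(512, 1, p, availability = "numeric"))
  expect_lt(abs(th_num - th[10]), 3)
})

test_that("resonance frequency matches the closed form and its numeric argmax", {
  p <- theory_params()
  fstar <- resonance_frequency(p)
  expect_equal(round(fstar, 2), 0.69)
  opt <- optimize(function(om) theta_hat(om, p), c(0.05, 100),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum / (2 * pi), fstar, tolerance = 1e-6)
  expect_equal(opt$maximum, 1 / sqrt(p$tau_rec * p$kappa), tolerance = 1e-6)
  # modulation depth B does not enter the resonance
  expect_equal(resonance_frequency(theory_params(B = 5)), fstar)
})

test_that("resonance scalings are linear in sqrt(tau_rec) and sqrt(P_v)", {
  tr <- seq(0.1, 2, length.out = 25)
  period <- sapply(tr, function(x)
    1 / resonance_frequency(theory_params(tau_rec = x)))
  expect_gt(summary(lm(period ~ sqrt(tr)))$r.squared, 0.99)
  pv <- seq(0.05, 1, length.out = 25)
  fs <- sapply(pv, function(x) resonance_frequency(theory_params(P_v = x)))
  expect_gt(summary(lm(fs ~ sqrt(pv)))$r.squared, 0.99)
})
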