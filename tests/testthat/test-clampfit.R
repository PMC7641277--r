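test_that("noiseless activation datasets lie exactly on the sigmoid", {
  pre <- channel_preset(v05 = -100, k = 10)
  d <- gen_activation_dataset(pre, seq(-140, -40, 10))
  # half-activation at v05 by definition
  expect_equal(d$current[d$v_m == -100], 0.5, tolerance = 1e-12)
  manual <- 0 + 1 / (1 + exp((d$v_m + 100) / 10))
  expect_rel_equal(d$current, manual, 1e-9)
  expect_error(gen_activation_dataset(pre, c(-140, -100, -40)), "at least 6")
  expect_error(channel_preset(k = -1), "k")
})

test_that("fit_boltzmann recovers exact parameters and rejects flat data", {
  d <- gen_activation_dataset(channel_preset(v05 = -100, k = 10))
  f <- fit_boltzmann(d)
  expect_equal(f$v05, -100, tolerance = 1e-6)
  expect_equal(f$k, 10, tolerance = 1e-6)
  flat <- data.frame(v_m = seq(-140, -40, 10), current = rep(1, 11))
  expect_error(fit_boltzmann(flat), "no sigmoid structure")
  expect_error(fit_boltzmann(d[1:3, ]), "5 distinct")
})

test_that("fit_boltzmann recovers every shipped holding-potential preset", {
  for (pre in hcn_presets()) {
    f <- fit_boltzmann(gen_activation_dataset(pre))
    expect_equal(f$v05, pre$v05, tolerance = 1e-5)
    expect_equal(f$k, pre$k, tolerance = 1e-5)
  }
})

test_that("fit recovers random noiseless presets to 1e-6 and normalization
           rescales plateaus", {
  set.seed(42)
  for (rep in 1:12) {
    v05 <- runif(1, -115, -65)
    k <- runif(1, 5, 15)
    pre <- channel_preset(v05 = v05, k = k)
    f <- fit_boltzmann(gen_activation_dataset(pre, seq(-145, -35, 10)))
    expect_equal(f$v05, v05, tolerance = 1e-6)
    expect_equal(f$k, k, tolerance = 1e-6)
  }
  # normalize = TRUE first scales by the maximum current
  pre <- channel_preset(v05 = -95, k = 9, imax = 800, imin = 0)
  d <- gen_activation_dataset(pre)
  f <- fit_boltzmann(d, normalize = TRUE)
  expect_equal(f$v05, -95, tolerance = 1e-5)
  # plateau slightly exceeds the largest normalized sample
  expect_lt(f$imax, 1.02)
  expect_gt(f$imax, 0.99)
})

test_that("fitted activation increases with hyperpolarization", {
  d <- gen_activation_dataset(channel_preset(v05 = -90, k = 12),
                              noise_sd = 0.02, seed = 7)
  f <- fit_boltzmann(d)
  vv <- seq(-140, -40, 1)
  expect_true(all(diff(predict(f, vv)) < 0))
})

test_that("noisy Boltzmann fits agree with the exhaustive grid oracle", {
  pre <- channel_preset(v05 = -100, k = 10)
  d <- gen_activation_dataset(pre, seq(-140, -40, 10), noise_sd = 0.03,
                              seed = 11)
  f <- fit_boltzmann(d)
  g <- grid_boltzmann(d$v_m, d$current,
                      seq(-110, -90, 0.1), seq(6, 14, 0.1))
  expect_lt(abs(f$v05 - g[["v05"]]), 0.5)
  expect_lt(abs(f$k - g[["k"]]), 0.5)
})

test_that("mean fitted v05 over noisy replicates stays within 1 mV", {
  pre <- channel_preset(v05 = -100.1, k = 10)
  v05s <- vapply(1:60, function(s) {
    d <- gen_activation_dataset(pre, seq(-140, -40, 10), noise_sd = 0.02,
                                seed = s)
    fit_boltzmann(d)$v05
  }, numeric(1))
  expect_lt(abs(mean(v05s) - (-100.1)), 1)
})

test_that("noiseless current traces follow the stated exponential forms", {
  # order 1: I = 2 + 3 exp(-t/0.5), no delay
  pre <- channel_preset(imax = 5, imin = 2, tau1 = 0.5, tau2 = 0.05,
                        delay = 0)
  tr <- gen_current_trace(pre, duration = 3, order = 1)
  t_at <- function(t) tr$values[round(t * tr$sampling_rate) + 1L]
  expect_equal(t_at(0.5), 2 + 3 * exp(-1), tolerance = 1e-9)
  tt <- trace_times(tr)
  expect_rel_equal(tr$values, 2 + 3 * exp(-tt / 0.5), 1e-9)
  # delay contract: samples before the delay hold the ideal t = delay value
  pre2 <- channel_preset(imax = 5, imin = 2, tau1 = 0.5, tau2 = 0.05,
                         delay = 0.05)
  tr2 <- gen_current_trace(pre2, duration = 3, order = 1)
  before <- trace_times(tr2) < 0.05
  expect_true(all(tr2$values[before] == tr2$values[1L]))
  expect_equal(tr2$values[1L], 5, tolerance = 1e-12)
  expect_error(gen_current_trace(pre, duration = 3, order = 3), "order")
  expect_error(gen_current_trace(pre, duration = 1, order = 1), "duration")
})

test_that("fit_exponential recovers single and double time constants", {
  pre <- channel_preset(imax = 5, imin = 2, tau1 = 0.5, tau2 = 0.05,
                        delay = 0)
  f1 <- fit_exponential(gen_current_trace(pre, duration = 3, order = 1),
                        order = 1)
  expect_equal(f1$iss, 2, tolerance = 1e-6)
  expect_equal(f1$amplitudes, 3, tolerance = 1e-5)
  expect_equal(f1$taus, 0.5, tolerance = 1e-6)

  pre2 <- channel_preset(imax = 4, imin = 1, tau1 = 1.0, tau2 = 0.1,
                         a1_frac = 0.6, delay = 0)
  f2 <- fit_exponential(gen_current_trace(pre2, duration = 7, order = 2),
                        order = 2)
  expect_lt(abs(f2$taus[1] - 1.0) / 1.0, 0.01)
  expect_lt(abs(f2$taus[2] - 0.1) / 0.1, 0.01)
  expect_false(f2$degenerate)
})

test_that("order-2 fits of single-tau data degenerate gracefully and match
           order 1", {
  pre <- channel_preset(imax = 5, imin = 2, tau1 = 0.5, tau2 = 0.05,
                        a1_frac = 1, delay = 0)
  tr <- gen_current_trace(pre, duration = 3, order = 2)   # a1_frac = 1
  f1 <- fit_exponential(tr, order = 1)
  f2 <- fit_exponential(tr, order = 2)
  expect_equal(f1$taus[1], 0.5, tolerance = 1e-4)
  # the dominant component of the order-2 fit matches the single tau
  j <- which.max(abs(f2$amplitudes))
  expect_equal(f2$taus[j], 0.5, tolerance = 0.01)
  expect_error(
    fit_exponential(uniform_trace(rep(2, 3000), 1000, "pA"), order = 1),
    "no exponential decay")
})

test_that("current density and calcium decomposition are exact arithmetic", {
  expect_equal(current_density(-450, 30), -15)
  expect_equal(current_density(0, 25), 0)
  expect_error(current_density(-450, 0), "> 0")
  expect_equal(ica_decompose(-20, -12), -8)
  expect_equal(ica_decompose(-12, -12), 0)
  expect_warning(ica_decompose(5, -12), "inward")
})
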