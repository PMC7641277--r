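test_that("planar waves map to linearly increasing activation times", {
  st <- gen_wave_stack(nrow = 10, ncol = 10, pitch_um = 100,
                       origin = c(1, 1), velocity_um_ms = 100,
                       frame_rate_hz = 2000)
  m <- activation_map(st)
  expect_equal(m$leading_site, c(1L, 1L))
  # absolute per-pixel times are within half a frame of the analytic truth
  abs_times <- m$times_ms + m$t_ref_ms
  err <- abs(abs_times - st$events$activation_ms)
  expect_lte(max(err, na.rm = TRUE), 0.5 * 1000 / st$frame_rate_hz + 1e-9)
})

test_that("activation-time differences equal distance over velocity", {
  st <- gen_wave_stack(nrow = 4, ncol = 11, pitch_um = 100,
                       origin = c(2, 1), velocity_um_ms = 100,
                       frame_rate_hz = 2000)
  m <- activation_map(st)
  # 10 pixels = 1000 um apart -> 10 ms later
  expect_equal(m$times_ms[2, 11] - m$times_ms[2, 1], 10, tolerance = 0.5)
})

test_that("a uniform flash yields an all-zero map", {
  # pad chosen off the frame grid so the simultaneous upstroke does not sit
  # exactly on a tie between two frame intervals
  st <- gen_wave_stack(nrow = 6, ncol = 6, origin = c(3, 3),
                       velocity_um_ms = Inf, frame_rate_hz = 2000,
                       pad_ms = 10.13)
  m <- activation_map(st)
  expect_lt(max(abs(m$times_ms), na.rm = TRUE), 1e-9)
})

test_that("maps are invariant to per-pixel affine rescaling", {
  # odd pitch/velocity keep upstroke centres away from exact frame
  # boundaries, where tie-breaking would be legitimately scale-sensitive
  st <- gen_wave_stack(nrow = 8, ncol = 8, pitch_um = 97, origin = c(2, 7),
                       velocity_um_ms = 83, frame_rate_hz = 2000, seed = 4)
  m1 <- activation_map(st)
  set.seed(1)
  st2 <- st
  gains <- matrix(runif(64, 0.5, 3), 8, 8)
  offs <- matrix(runif(64, -1, 5), 8, 8)
  for (r in 1:8) for (cc in 1:8) {
    st2$frames[r, cc, ] <- gains[r, cc] * st2$frames[r, cc, ] + offs[r, cc]
  }
  m2 <- activation_map(st2)
  expect_equal(m2$times_ms, m1$times_ms)
})

test_that("noisy planar waves recover the conduction velocity within 5%", {
  st <- gen_wave_stack(nrow = 14, ncol = 14, pitch_um = 100,
                       origin = c(1, 1), velocity_um_ms = 120,
                       frame_rate_hz = 2000, noise_sd = 0.05, seed = 9)
  m <- activation_map(st, smooth_frames = 2)
  dist_um <- sqrt((row(m$times_ms) - 1)^2 + (col(m$times_ms) - 1)^2) * 100
  ok <- m$mask & dist_um > 0
  fit <- stats::lm(as.vector(m$times_ms[ok]) ~ as.vector(dist_um[ok]))
  v_hat <- 1 / stats::coef(fit)[[2]]
  expect_lt(abs(v_hat - 120) / 120, 0.05)
})

test_that("optical SACT is the ROI activation delay and is antisymmetric", {
  st <- gen_wave_stack(nrow = 4, ncol = 13, pitch_um = 100,
                       origin = c(2, 1), velocity_um_ms = 100,
                       frame_rate_hz = 2000)
  m <- activation_map(st)
  san <- cbind(2, 1:2)
  ct <- cbind(2, 12:13)
  d <- optical_sact(m, san, ct)
  expect_equal(d, 11, tolerance = 0.5)           # 1100 um at 100 um/ms
  expect_equal(optical_sact(m, ct, san), -d)
  expect_equal(optical_sact(m, san, san), 0)
  empty <- matrix(FALSE, 4, 13)
  expect_error(optical_sact(m, san, empty), "no valid pixel")
})

test_that("pacemaker shift normalizes pixel distance by preparation size", {
  expect_equal(pacemaker_shift(c(1, 1), c(1, 11), pitch_um = 100,
                               preparation_extent_um = 5000), 0.2)
  expect_equal(pacemaker_shift(c(3, 4), c(3, 4), 100, 5000), 0)
  expect_error(pacemaker_shift(c(1, 1), c(2, 2), 100, 0), "> 0")
  # programmed shifted origin recovers exactly through the generator
  st1 <- gen_wave_stack(nrow = 9, ncol = 9, origin = c(5, 5),
                        velocity_um_ms = 100, frame_rate_hz = 2000)
  st2 <- gen_wave_stack(nrow = 9, ncol = 9, origin = c(5, 9),
                        velocity_um_ms = 100, frame_rate_hz = 2000)
  a <- activation_map(st1)$leading_site
  b <- activation_map(st2)$leading_site
  expect_equal(pacemaker_shift(a, b, 100, 4000), 400 / 4000)
})

test_that("dF/F0 normalization matches hand arithmetic", {
  # background 10, baseline 100 (net 90), peak 190 (net 180) -> 1.0
  v <- c(rep(100, 100), seq(100, 190, length.out = 20), rep(190, 30),
         rep(100, 50))
  tr <- uniform_trace(v, 100, units = "a.u.")
  r <- dff(tr, background = 10, baseline_window = c(0, 0.99))
  expect_equal(r$f0, 90)
  expect_equal(max(r$trace$values), 1, tolerance = 1e-12)
  flat <- uniform_trace(rep(50, 200), 100, units = "a.u.")
  r2 <- dff(flat, background = 10, baseline_window = c(0, 1))
  expect_true(all(abs(r2$trace$values) < 1e-12))
  expect_error(dff(flat, background = 60, baseline_window = c(0, 1)),
               "F0")
  # programmed transient amplitude recovers exactly
  amp <- 2.5; f0 <- 40; bg <- 7
  v3 <- bg + f0 * c(rep(1, 50), 1 + amp * sin(seq(0, pi, length.out = 51)))
  r3 <- dff(uniform_trace(v3, 100, units = "a.u."), bg, c(0, 0.49))
  expect_equal(max(r3$trace$values), amp, tolerance = 1e-9)
})

test_that("subthreshold cell density is count per area", {
  expect_equal(subthreshold_density(5, 440^2), 5 / 193600)
  expect_equal(subthreshold_density(0, 1000), 0)
  expect_error(subthreshold_density(3, 0), "> 0")
})

test_that("wave generator rejects bad geometry", {
  expect_error(gen_wave_stack(origin = c(0, 1)), "outside")
  expect_error(gen_wave_stack(velocity_um_ms = 0), "> 0")
})
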