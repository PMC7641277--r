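test_that("rate summaries and the 50-bin histogram behave as specified", {
  b <- gen_rr_series(1200, mean_rr = 100)          # constant 600 bpm
  s <- summarize_rate(b, histogram = TRUE)
  expect_equal(s$mean_hr, 600)
  expect_equal(s$min_hr, 600)
  expect_equal(s$max_hr, 600)
  # all histogram mass in the bin containing 600 bpm
  expect_equal(sum(s$histogram$counts), length(s$window_means))
  hit <- which(s$histogram$counts > 0)
  expect_length(hit, 1L)
  expect_true(s$histogram$breaks[hit] <= 600 &&
                600 <= s$histogram$breaks[hit + 1L])
  expect_equal(diff(s$histogram$breaks)[1], (950 - 150) / 50)
  # programmed mean recovers
  b2 <- gen_rr_series(3000, mean_rr = 120, white_sd = 2, seed = 4)
  s2 <- summarize_rate(b2)
  expect_lt(abs(s2$mean_hr - 60000 / 120), 1)
})

test_that("SDNN/RMSSD closed forms, translation invariance and scale
           equivariance", {
  b <- beat_series(rep(100, 700))
  td <- time_domain(b, segment_minutes = 1, n_segments = 1)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)

  alt <- beat_series(rep(c(100, 110), 400))
  td2 <- time_domain(alt, segment_minutes = 1, n_segments = 1)
  expect_equal(td2$rmssd, 10, tolerance = 1e-9)

  # invariances over RR values, with beat times held fixed so the same
  # beats fall into the analysis segment
  set.seed(9)
  rr <- 100 + rnorm(800, 0, 4)
  ts <- cumsum(rr) / 1000
  t1 <- time_domain(beat_series(rr, t_s = ts), segment_minutes = 1,
                    n_segments = 1)
  t2 <- time_domain(beat_series(rr + 50, t_s = ts), segment_minutes = 1,
                    n_segments = 1)
  expect_equal(t1$sdnn, t2$sdnn, tolerance = 1e-9)
  expect_equal(t1$rmssd, t2$rmssd, tolerance = 1e-9)
  t3 <- time_domain(beat_series(rr * 3, t_s = ts), segment_minutes = 1,
                    n_segments = 1)
  expect_equal(t3$sdnn, 3 * t1$sdnn, tolerance = 1e-9)
  expect_equal(t3$rmssd, 3 * t1$rmssd, tolerance = 1e-9)
  expect_error(time_domain(beat_series(rep(100, 20)), 10, 3), "required")
})

test_that("spectral band powers add to total power and locate modulation", {
  b <- gen_rr_series(1300, mean_rr = 100, lf_amp = 10, lf_freq = 1.0,
                     seed = 2)
  s <- spectral_hrv(b)
  expect_lt(abs(s$vlf + s$lf + s$hf - s$tp) / s$tp, 1e-9)
  expect_gte(s$lf / (s$tp - s$vlf), 0.9)
  # peak within one grid bin of the programmed frequency
  expect_lt(abs(s$freq[which.max(s$power)] - 1.0), s$resolution + 1e-12)

  b2 <- gen_rr_series(1300, mean_rr = 100, hf_amp = 8, hf_freq = 2.5,
                      seed = 3)
  s2 <- spectral_hrv(b2)
  pk <- s2$freq[which.max(s2$power)]
  expect_true(pk > 1.5 && pk < 4.0)
  expect_lt(abs(pk - 2.5), s2$resolution + 1e-12)
  expect_gt(s2$hf, s2$lf)

  # the package PSD and a direct DFT on the same resampled series agree on
  # where the power sits
  dp <- direct_periodogram(
    stats::spline(b$t_s, b$rr_ms,
                  xout = seq(b$t_s[1], by = 0.05, length.out = 2048))$y, 20)
  expect_lt(abs(dp$freq[which.max(dp$power[-1])] + 0 - 1.0), 0.05)
})

test_that("degenerate spectral inputs are rejected or collapse to zero", {
  s0 <- spectral_hrv(gen_rr_series(1300, mean_rr = 100))
  expect_lt(s0$tp, 1e-12)
  short <- gen_rr_series(100, mean_rr = 100)
  expect_error(spectral_hrv(short), "segment too short")
  bad <- beat_series(rep(100, 1200), t_s = rev(seq_len(1200)))
  expect_error(spectral_hrv(bad), "increasing")
})

test_that("poincare pairs lag the series by one beat", {
  b <- beat_series(c(100, 110, 105))
  p <- poincare(b)
  expect_equal(p$rr_n, c(100, 110))
  expect_equal(p$rr_n1, c(110, 105))
  const <- poincare(beat_series(rep(90, 50)))
  expect_true(all(const$rr_n == const$rr_n1))
  expect_equal(nrow(poincare(beat_series(rep(90, 50)))), 49L)
  expect_equal(nrow(poincare(beat_series(rep(90, 50)), n_points = 10)), 10L)
})

test_that("sinus pauses use a strict doubling threshold", {
  rr <- rep(100, 50); rr[25] <- 250
  expect_equal(nrow(detect_pauses(beat_series(rr), 100)), 1L)
  rr2 <- rep(100, 50); rr2[25] <- 200          # exactly 2x: not a pause
  expect_equal(nrow(detect_pauses(beat_series(rr2), 100)), 0L)
  # three injected pauses recovered through the generator
  b <- gen_rr_series(300, mean_rr = 100, white_sd = 1,
                     pause_times = c(50, 150, 250), pause_factor = 2.5,
                     seed = 6)
  expect_equal(nrow(detect_pauses(b, 100)), 3L)
})
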