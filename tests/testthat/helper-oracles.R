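# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths.

# exhaustive grid search for the Boltzmann (v05, k); for each grid node the
# plateaus are solved by conditional linear least squares
grid_boltzmann <- function(v, i, v05_grid, k_grid) {
  best <- c(v05 = NA, k = NA, rss = Inf)
  for (v05 in v05_grid) {
    for (k in k_grid) {
      s <- 1 / (1 + exp((v - v05) / k))
      X <- cbind(1, s)
      cf <- tryCatch(qr.solve(X, i), error = function(e) NULL)
      if (is.null(cf)) next
      rss <- sum((i - X %*% cf)^2)
      if (rss < best["rss"]) best <- c(v05 = v05, k = k, rss = rss)
    }
  }
  best
}

# brute-force scan of every beat triple for baroreflex sequences
brute_sequences <- function(beats, sbp_thr = 0.5, rr_thr = 2, delay = 1,
                            min_r = 0.85) {
  sbp <- beats$sbp_mmhg; rr <- beats$rr_ms
  n <- length(sbp)
  up <- down <- list()
  for (s in seq_len(n - 2 - delay)) {
    ds <- diff(sbp[s + 0:2])
    dr <- diff(rr[s + delay + 0:2])
    x <- sbp[s + 0:2]; y <- rr[s + delay + 0:2]
    sl <- stats::cov(x, y) / stats::var(x)
    r <- suppressWarnings(stats::cor(x, y))
    if (!is.finite(r) || abs(r) <= min_r) next
    if (all(ds >= sbp_thr) && all(dr >= rr_thr)) {
      up[[length(up) + 1]] <- c(start = s, slope = sl)
    } else if (all(ds <= -sbp_thr) && all(dr <= -rr_thr)) {
      down[[length(down) + 1]] <- c(start = s, slope = sl)
    }
  }
  list(up = do.call(rbind, up), down = do.call(rbind, down))
}

# direct one-sided periodogram (plain DFT, boxcar) on an already-resampled
# series; used to check where spectral power concentrates
direct_periodogram <- function(y, fs) {
  n <- length(y)
  p <- abs(stats::fft(y - mean(y)))^2 / (fs * n)
  half <- floor(n / 2) + 1
  p <- p[seq_len(half)]
  p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  list(freq = seq(0, fs / 2, length.out = half), power = p)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), 1e-12), tol)
}
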