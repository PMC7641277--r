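#' Heart-rate summary over 10-s windows, with optional histogram
#'
#' Instantaneous heart rate per beat is `60000 / RR_ms`. Mean heart rate is
#' computed in consecutive 10-s windows; the summary reports the mean,
#' minimum and maximum of those window means, and optionally their
#' histogram in 50 equal bins spanning 150--950 bpm (16 bpm per bin).
#'
#' @param beats a [beat_series()] covering at least 20 s.
#' @param histogram also return the 50-bin histogram of 10-s mean rates.
#' @param window_s window length, s.
#' @param hist_range,hist_bins histogram range (bpm) and bin count.
#' @return An object of class `hr_summary`: `mean_hr`, `min_hr`, `max_hr`
#'   (bpm over window means), `window_means`, and optionally `histogram`
#'   (`breaks`, `mids`, `counts`).
#' @export
summarize_rate <- function(beats, histogram = FALSE, window_s = 10,
                           hist_range = c(150, 950), hist_bins = 50) {
  stopifnot(inherits(beats, "beat_series"))
  if (any(beats$rr_ms <= 0)) stop("RR intervals must be > 0")
  span <- max(beats$t_s) - min(beats$t_s)
  if (span < 2 * window_s) {
    stop("series must cover at least two windows (", 2 * window_s, " s)")
  }
  hr <- 60000 / beats$rr_ms
  win <- floor((beats$t_s - min(beats$t_s)) / window_s)
  wm <- as.numeric(tapply(hr, win, mean))
  out <- list(mean_hr = mean(wm), min_hr = min(wm), max_hr = max(wm),
              window_means = wm)
  if (histogram) {
    breaks <- seq(hist_range[1], hist_range[2], length.out = hist_bins + 1)
    inside <- wm >= hist_range[1] & wm <= hist_range[2]
    h <- graphics::hist(wm[inside], breaks = breaks, plot = FALSE)
    out$histogram <- list(breaks = breaks, mids = h$mids, counts = h$counts)
  }
  structure(out, class = "hr_summary")
}

#' @export
print.hr_summary <- function(x, ...) {
  cat(sprintf("hr_summary: mean %.1f, min %.1f, max %.1f bpm (%d windows)\n",
              x$mean_hr, x$min_hr, x$max_hr, length(x$window_means)))
  invisible(x)
}

#' Time-domain heart-rate variability
#'
#' SDNN (standard deviation of RR intervals) and RMSSD (root mean square of
#' successive RR differences) are computed per segment of
#' `segment_minutes` and averaged over `n_segments` consecutive segments.
#' The caller supplies a cleaned series (normal beats in sinus rhythm); an
#' optional artifact filter drops RR values outside mean +/- 4 SD.
#'
#' @param beats a [beat_series()].
#' @param segment_minutes segment length in minutes.
#' @param n_segments number of consecutive segments to average.
#' @param artifact_filter drop RR outside mean +/- 4 SD before analysis.
#' @return An object of class `hrv_time`: `sdnn`, `rmssd` (ms, averaged),
#'   per-segment values, and per-beat heart-rate summaries (`mean_hr`,
#'   `min_hr`, `max_hr`, bpm).
#' @export
time_domain <- function(beats, segment_minutes = 10, n_segments = 3,
                        artifact_filter = FALSE) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  t_s <- beats$t_s
  if (artifact_filter) {
    keep <- abs(rr - mean(rr)) <= 4 * stats::sd(rr)
    rr <- rr[keep]; t_s <- t_s[keep]
  }
  seg_len <- segment_minutes * 60
  need <- n_segments * seg_len
  span <- max(t_s) - min(t_s)
  if (span < need) {
    stop("series covers ", round(span, 1), " s but ", need,
         " s are required for ", n_segments, " segment(s)")
  }
  rel <- t_s - min(t_s)
  sdnn <- rmssd <- numeric(n_segments)
  for (j in seq_len(n_segments)) {
    sel <- rel >= (j - 1) * seg_len & rel < j * seg_len
    x <- rr[sel]
    if (length(x) < 3L) stop("segment ", j, " contains fewer than 3 beats")
    sdnn[j] <- stats::sd(x)
    rmssd[j] <- sqrt(mean(diff(x)^2))
  }
  hr <- 60000 / rr
  structure(
    list(sdnn = mean(sdnn), rmssd = mean(rmssd),
         sdnn_per_segment = sdnn, rmssd_per_segment = rmssd,
         mean_hr = mean(hr), min_hr = min(hr), max_hr = max(hr)),
    class = "hrv_time")
}

#' @export
print.hrv_time <- function(x, ...) {
  cat(sprintf("hrv_time: SDNN %.2f ms, RMSSD %.2f ms (%d segment(s))\n",
              x$sdnn, x$rmssd, length(x$sdnn_per_segment)))
  invisible(x)
}

#' Frequency-domain heart-rate variability
#'
#' The murine HRV spectral pipeline: a 103-s RR tachogram is resampled by
#' cubic spline interpolation on a 50-ms (20 Hz) grid, linearly detrended
#' over the 2048-sample analysis stretch, split into three half-overlapping
#' 1024-sample segments, Hamming-windowed, and the window-power-compensated
#' one-sided periodograms are averaged. Band powers are trapezoidal
#' integrals of the power spectral density over VLF 0--0.4 Hz, LF
#' 0.4--1.5 Hz and HF 1.5--4.0 Hz; total power is the integral over
#' 0--4 Hz, so VLF + LF + HF = TP by construction.
#'
#' @param beats a [beat_series()] in stable sinus rhythm.
#' @param segment_s tachogram length, s (103 s gives 2060 resampled points,
#'   just covering the 2048 needed for the three windows).
#' @param resample_ms spline resampling interval, ms.
#' @return An object of class `psd_result`: `freq` (Hz), `power`
#'   (ms^2/Hz), `tp`, `vlf`, `lf`, `hf` (ms^2), `resolution` (Hz).
#' @export
spectral_hrv <- function(beats, segment_s = 103, resample_ms = 50) {
  stopifnot(inherits(beats, "beat_series"))
  t_s <- beats$t_s
  rr <- beats$rr_ms
  if (is.unsorted(t_s, strictly = TRUE)) {
    stop("beat times must be strictly increasing")
  }
  dt <- resample_ms / 1000
  fs <- 1 / dt
  nfft <- 1024L
  need <- 2L * nfft                      # three half-overlapping windows
  # sanity: the stated segment length must cover the analysis stretch
  if (floor(segment_s / dt) < need) {
    stop("segment of ", segment_s, " s gives fewer than ", need,
         " resampled points")
  }
  t_end <- t_s[1L] + segment_s
  sel <- t_s <= t_end + dt
  if (max(t_s) < t_end) {
    stop("segment too short: series covers ", round(max(t_s) - t_s[1L], 1),
         " s of the ", segment_s, " s required")
  }
  grid <- seq(t_s[1L], by = dt, length.out = floor(segment_s / dt))
  y <- stats::spline(t_s[sel], rr[sel], xout = grid, method = "fmm")$y
  y <- y[seq_len(need)]

  # linear detrend over the analysis stretch
  xs <- seq_along(y)
  y <- stats::resid(stats::lm(y ~ xs))

  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))
  wpow <- sum(w^2)
  starts <- c(1L, nfft / 2L + 1L, nfft + 1L)
  psd <- 0
  for (s0 in starts) {
    seg <- y[s0:(s0 + nfft - 1L)] * w
    p <- abs(stats::fft(seg))^2 / (fs * wpow)
    psd <- psd + p[seq_len(nfft / 2L + 1L)]
  }
  psd <- psd / length(starts)
  psd[2:(nfft / 2L)] <- 2 * psd[2:(nfft / 2L)]   # one-sided
  freq <- seq(0, fs / 2, length.out = nfft / 2L + 1L)

  band <- function(f1, f2) trapz_band(freq, psd, f1, f2)
  vlf <- band(0, 0.4); lf <- band(0.4, 1.5); hf <- band(1.5, 4.0)
  structure(
    list(freq = freq, power = psd, tp = vlf + lf + hf,
         vlf = vlf, lf = lf, hf = hf, resolution = fs / nfft),
    class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat("psd_result (ms^2):\n")
  cat(sprintf("  TP %.4g | VLF %.4g | LF %.4g | HF %.4g\n",
              x$tp, x$vlf, x$lf, x$hf))
  cat(sprintf("  grid resolution %.4g Hz\n", x$resolution))
  invisible(x)
}

#' @export
plot.psd_result <- function(x, ...) {
  sel <- x$freq <= 4
  graphics::plot(x$freq[sel], x$power[sel], type = "l",
                 xlab = "frequency (Hz)", ylab = "PSD (ms^2/Hz)", ...)
  graphics::abline(v = c(0.4, 1.5), lty = 3)
  invisible(x)
}

# trapezoidal band power with interpolated band edges, so that adjacent
# bands sum exactly to the integral over their union
trapz_band <- function(freq, psd, f1, f2) {
  pf <- stats::approx(freq, psd, xout = c(f1, f2))$y
  inside <- freq > f1 & freq < f2
  xs <- c(f1, freq[inside], f2)
  ys <- c(pf[1L], psd[inside], pf[2L])
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
}

#' Poincaré pairs of successive RR intervals
#'
#' @param beats a [beat_series()] with at least 2 beats.
#' @param n_points maximum number of pairs returned (the murine telemetry
#'   convention uses 20,000 points).
#' @return Data frame with columns `rr_n` and `rr_n1` (ms).
#' @export
poincare <- function(beats, n_points = 20000) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  if (length(rr) < 2L) stop("need at least 2 beats")
  n <- min(length(rr) - 1L, n_points)
  data.frame(rr_n = rr[seq_len(n)], rr_n1 = rr[seq_len(n) + 1L])
}

#' Detect sinus pauses in an RR series
#'
#' A sinus pause is a beat whose RR interval strictly exceeds twice the
#' reference mean RR.
#'
#' @param beats a [beat_series()].
#' @param reference_mean reference mean RR, ms (> 0); e.g. the mean RR
#'   during stimulation.
#' @return Data frame of pause events: `beat`, `t_s`, `rr_ms`.
#' @export
detect_pauses <- function(beats, reference_mean) {
  stopifnot(inherits(beats, "beat_series"))
  if (reference_mean <= 0) stop("'reference_mean' must be > 0")
  hit <- beats$rr_ms > 2 * reference_mean
  out <- as.data.frame(beats)[hit, c("beat", "t_s", "rr_ms"), drop = FALSE]
  rownames(out) <- NULL
  out
}
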