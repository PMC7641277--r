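#' Synthetic RR tachogram
#'
#' Builds an RR-interval series with sinusoidal low- and high-frequency
#' modulation plus white noise:
#' `RR_i = mean_rr + lf_amp sin(2 pi lf_freq t_i) + hf_amp sin(2 pi hf_freq
#' t_i) + e_i`, with beat times the cumulative sums of the RR intervals.
#' Beats listed in `pause_times` are multiplied by `pause_factor` to inject
#' detectable sinus pauses.
#'
#' @param n_beats number of beats (>= 10).
#' @param mean_rr mean RR interval, ms.
#' @param lf_amp,lf_freq low-frequency modulation amplitude (ms) and
#'   frequency (Hz, within 0--4).
#' @param hf_amp,hf_freq high-frequency modulation amplitude (ms) and
#'   frequency (Hz, within 0--4).
#' @param white_sd white-noise SD, ms.
#' @param pause_times integer beat indices receiving a pause.
#' @param pause_factor multiplier applied at pause beats (> 2 makes the
#'   pause detectable by [detect_pauses()]).
#' @param seed integer seed.
#' @return A [beat_series()].
#' @export
gen_rr_series <- function(n_beats, mean_rr = 100,
                          lf_amp = 0, lf_freq = 1.0,
                          hf_amp = 0, hf_freq = 2.5,
                          white_sd = 0, pause_times = integer(0),
                          pause_factor = 2.5, seed = 1) {
  if (n_beats < 10) stop("'n_beats' must be at least 10")
  if (mean_rr <= 0) stop("'mean_rr' must be > 0")
  if (any(c(lf_freq, hf_freq) < 0) || any(c(lf_freq, hf_freq) > 4)) {
    stop("modulation frequencies must lie within 0-4 Hz")
  }
  withr_seed(seed)
  eps <- if (white_sd > 0) stats::rnorm(n_beats, 0, white_sd) else
    numeric(n_beats)
  rr <- numeric(n_beats)
  t_i <- 0
  for (i in seq_len(n_beats)) {
    rr[i] <- mean_rr +
      lf_amp * sin(2 * pi * lf_freq * t_i) +
      hf_amp * sin(2 * pi * hf_freq * t_i) + eps[i]
    if (i %in% pause_times) rr[i] <- rr[i] * pause_factor
    t_i <- t_i + rr[i] / 1000
  }
  if (any(rr <= 0)) stop("generated RR intervals must all be > 0")
  beat_series(rr)
}

#' Synthetic beat-aligned SBP--RR series with programmed baroreflex sequences
#'
#' Emits a flat baseline of systolic blood pressure (SBP) and RR intervals
#' into which `n_up` up sequences and `n_down` down sequences are written:
#' three consecutive beats of monotone SBP change of `step_mmhg` per beat,
#' with the RR interval responding `delay_beats` later at the programmed
#' slope. Sequences are spaced with buffer beats so they cannot overlap.
#' The programmed truth is attached as `attr(, "events")`.
#'
#' @param n_beats total number of beats.
#' @param n_up,n_down numbers of programmed up and down sequences.
#' @param slope_up,slope_down programmed reflex slopes, ms/mmHg (>= 0).
#' @param step_mmhg SBP change per beat within a sequence, mmHg (>= 0.5).
#' @param delay_beats beat lag of the RR response (the sequence method
#'   convention for mice is 1).
#' @param sbp_noise,rr_noise additive noise SDs, mmHg and ms.
#' @param baseline_sbp,baseline_rr baseline levels, mmHg and ms.
#' @param seed integer seed.
#' @return A [beat_series()] with an `sbp_mmhg` column.
#' @export
gen_bp_rr <- function(n_beats, n_up = 5, n_down = 5,
                      slope_up = 4, slope_down = 4, step_mmhg = 2,
                      delay_beats = 1, sbp_noise = 0, rr_noise = 0,
                      baseline_sbp = 120, baseline_rr = 100, seed = 1) {
  if (step_mmhg < 0.5) stop("'step_mmhg' must be >= 0.5 for detectability")
  if (slope_up < 0 || slope_down < 0) stop("slopes must be >= 0")
  spacing <- 3L + as.integer(delay_beats) + 4L
  n_seq <- n_up + n_down
  first_start <- 3L
  need <- first_start + n_seq * spacing + 2L
  if (n_seq > 0 && n_beats < need) {
    stop("programmed sequences would overlap: need at least ", need,
         " beats for ", n_seq, " sequences")
  }
  withr_seed(seed)
  sbp <- rep(baseline_sbp, n_beats)
  rr <- rep(baseline_rr, n_beats)
  types <- character(0)
  starts <- integer(0)
  if (n_seq > 0) {
    types <- sample(c(rep("up", n_up), rep("down", n_down)))
    starts <- first_start + (seq_len(n_seq) - 1L) * spacing
    for (j in seq_len(n_seq)) {
      s <- starts[j]
      sgn <- if (types[j] == "up") 1 else -1
      slope <- if (types[j] == "up") slope_up else slope_down
      dsbp <- sgn * step_mmhg * (0:2)
      sbp[s + 0:2] <- baseline_sbp + dsbp
      rr[s + delay_beats + 0:2] <- baseline_rr + slope * dsbp
    }
  }
  if (sbp_noise > 0) sbp <- sbp + stats::rnorm(n_beats, 0, sbp_noise)
  if (rr_noise > 0) rr <- rr + stats::rnorm(n_beats, 0, rr_noise)
  out <- beat_series(rr, sbp_mmhg = sbp)
  attr(out, "events") <- data.frame(
    start = starts,
    type = if (length(starts)) types else character(0),
    slope = if (length(starts)) {
      ifelse(types == "up", slope_up, slope_down)
    } else numeric(0))
  out
}
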