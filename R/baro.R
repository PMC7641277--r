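#' Baroreflex sequence analysis of beat-aligned SBP and RR series
#'
#' Scans every triple of consecutive beats for spontaneous baroreflex
#' sequences: an up sequence is three beats with each systolic-blood-
#' pressure (SBP) step an increase of at least `sbp_threshold`, with the RR
#' interval `delay` beats later increasing by at least `rr_threshold` at
#' each step; down sequences mirror this with decreases. For each
#' qualifying triple the reflex slope is the least-squares regression of
#' the RR triple on the SBP triple, retained only when the correlation
#' satisfies `|r| > min_r`. Overlapping triples count as separate
#' sequences.
#'
#' @param beats a [beat_series()] with an `sbp_mmhg` column.
#' @param sbp_threshold minimum SBP change per step, mmHg.
#' @param rr_threshold minimum RR change per step, ms.
#' @param delay RR response lag in beats.
#' @param min_r minimum absolute correlation of the RR/SBP regression.
#' @param exclusions optional data frame of beat-index intervals
#'   (`start`, `end`) to exclude, e.g. arrhythmic stretches.
#' @return An object of class `sequence_result`: data frames `up` and
#'   `down` (columns `start`, `slope`, `r`, `sbp1..3`, `rr1..3`), counts
#'   `n_up`, `n_down`, and `mean_slope_up`, `mean_slope_down` (ms/mmHg).
#' @export
scan_sequences <- function(beats, sbp_threshold = 0.5, rr_threshold = 2,
                           delay = 1, min_r = 0.85, exclusions = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(beats$sbp_mmhg)) stop("series has no 'sbp_mmhg' column")
  sbp <- beats$sbp_mmhg
  rr <- beats$rr_ms
  n <- length(sbp)
  if (n < 3L + delay) stop("series too short for any triple")

  excluded <- rep(FALSE, n)
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (j in seq_len(nrow(exclusions))) {
      lo <- max(1L, exclusions$start[j])
      hi <- min(n, exclusions$end[j])
      if (hi >= lo) excluded[lo:hi] <- TRUE
    }
  }

  i_max <- n - 2L - delay
  i <- seq_len(i_max)
  d1 <- sbp[i + 1L] - sbp[i]
  d2 <- sbp[i + 2L] - sbp[i + 1L]
  r1 <- rr[i + delay + 1L] - rr[i + delay]
  r2 <- rr[i + delay + 2L] - rr[i + delay + 1L]
  touch_excl <- excluded[i] | excluded[i + 1L] | excluded[i + 2L] |
    excluded[i + delay] | excluded[i + delay + 1L] | excluded[i + delay + 2L]

  cand_up <- which(d1 >= sbp_threshold & d2 >= sbp_threshold &
                     r1 >= rr_threshold & r2 >= rr_threshold & !touch_excl)
  cand_dn <- which(d1 <= -sbp_threshold & d2 <= -sbp_threshold &
                     r1 <= -rr_threshold & r2 <= -rr_threshold & !touch_excl)

  collect <- function(cand) {
    rows <- lapply(cand, function(s) {
      x <- sbp[s + 0:2]
      y <- rr[s + delay + 0:2]
      slope <- stats::cov(x, y) / stats::var(x)
      r <- stats::cor(x, y)
      data.frame(start = s, slope = slope, r = r,
                 sbp1 = x[1], sbp2 = x[2], sbp3 = x[3],
                 rr1 = y[1], rr2 = y[2], rr3 = y[3])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(start = integer(0), slope = numeric(0),
                        r = numeric(0), sbp1 = numeric(0), sbp2 = numeric(0),
                        sbp3 = numeric(0), rr1 = numeric(0),
                        rr2 = numeric(0), rr3 = numeric(0))
    }
    out[abs(out$r) > min_r, , drop = FALSE]
  }
  up <- collect(cand_up)
  down <- collect(cand_dn)
  structure(
    list(up = up, down = down, n_up = nrow(up), n_down = nrow(down),
         mean_slope_up = if (nrow(up)) mean(up$slope) else NA_real_,
         mean_slope_down = if (nrow(down)) mean(down$slope) else NA_real_),
    class = "sequence_result")
}

#' @export
print.sequence_result <- function(x, ...) {
  cat(sprintf("sequence_result: %d up, %d down\n", x$n_up, x$n_down))
  cat(sprintf("  mean slope up %.3g, down %.3g ms/mmHg\n",
              x$mean_slope_up, x$mean_slope_down))
  invisible(x)
}
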