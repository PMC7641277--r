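#' Synthetic premature-atrial-stimulation table
#'
#' Builds the A1A1/A1A2/A2A3/A3A4 interval table of a premature-stimulation
#' protocol with a programmed sinus cycle length (SCL) and sinoatrial
#' conduction time (SACT). For coupling intervals at or above `reset_onset`
#' the pause is fully compensatory (`A2A3 = 2 SCL - A1A2`); for couplings in
#' the reset zone (`snerp < A1A2 < reset_onset`) the premature beat resets
#' the node and the return cycle sits on the plateau
#' `A2A3 = SCL + 2 SACT`. The post-return cycle A3A4 equals the SCL.
#'
#' @param scl spontaneous sinus cycle length (A1A1), ms.
#' @param sact programmed sinoatrial conduction time, ms (> 0).
#' @param reset_onset longest A1A2 that resets the node, ms.
#' @param snerp coupling below which there is no atrial capture, ms.
#' @param couplings A1A2 coupling intervals, ms.
#' @param jitter_sd measurement jitter SD added to every interval, ms.
#' @param allow_noncapture keep couplings at or below `snerp` as
#'   non-captured rows (`captured = FALSE`, NA return cycle) instead of
#'   erroring.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return A data frame of class `premature_stim_table` with columns
#'   `A1A1`, `A1A2`, `A2A3`, `A3A4`, `captured`.
#' @export
gen_premature_stim <- function(scl = 200, sact = 25, reset_onset = 160,
                               snerp = 60,
                               couplings = seq(70, 190, by = 10),
                               jitter_sd = 0, allow_noncapture = FALSE,
                               seed = 1) {
  if (!(snerp < reset_onset && reset_onset < scl)) {
    stop("need snerp < reset_onset < scl")
  }
  if (sact <= 0) stop("'sact' must be > 0")
  couplings <- as.numeric(couplings)
  bad <- couplings <= snerp
  if (any(bad) && !allow_noncapture) {
    stop("couplings at or below snerp (", snerp,
         " ms) do not capture the atrium; set allow_noncapture = TRUE ",
         "to keep them")
  }
  if (any(couplings >= scl)) {
    stop("couplings must be premature (A1A2 < A1A1)")
  }
  n <- length(couplings)
  a2a3 <- ifelse(couplings >= reset_onset,
                 2 * scl - couplings,      # fully compensatory pause
                 scl + 2 * sact)           # reset plateau
  a2a3[bad] <- NA_real_
  tab <- data.frame(A1A1 = rep(scl, n), A1A2 = couplings,
                    A2A3 = a2a3, A3A4 = rep(scl, n),
                    captured = !bad)
  if (jitter_sd > 0) {
    withr_seed(seed)
    for (cl in c("A1A1", "A2A3", "A3A4")) {
      tab[[cl]] <- tab[[cl]] + stats::rnorm(n, 0, jitter_sd)
    }
  }
  attr(tab, "truth") <- list(scl = scl, sact = sact,
                             reset_onset = reset_onset, snerp = snerp)
  class(tab) <- c("premature_stim_table", "data.frame")
  tab
}

#' Synthetic AV-conduction premature-stimulation table
#'
#' Emits (A1A2, V1V2, H1H2, A2V2) rows emulating the response of the AV
#' conduction system to premature atrial stimulation: above the relative
#' refractory period V1V2 tracks A1A2 one-to-one; below it AV-nodal delay
#' grows so that V1V2 passes through a programmed minimum (the functional
#' refractory period, FRP) and rises again towards block.
#'
#' @param couplings A1A2 intervals, ms, spanning the refractory curve.
#' @param rrp relative refractory period: A1A2 below which conduction
#'   delay accrues, ms.
#' @param frp programmed functional refractory period (minimum V1V2), ms.
#' @param base_avd baseline AV conduction delay (A2V2 at long couplings), ms.
#' @param jitter_sd measurement jitter SD, ms.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return A data frame of class `premature_stim_table` with columns
#'   `A1A2`, `V1V2`, `H1H2`, `A2V2`.
#' @export
gen_av_table <- function(couplings = seq(60, 140, by = 5), rrp = 100,
                         frp = 80, base_avd = 40, jitter_sd = 0, seed = 1) {
  stopifnot(frp < rrp, base_avd > 0)
  a1a2 <- as.numeric(couplings)
  # below the RRP the AV delay increment grows quadratically; with this
  # scaling the V1V2 curve has its minimum value exactly at the programmed
  # FRP (attained at A1A2 = 2 frp - rrp)
  delay_inc <- ifelse(a1a2 < rrp, (rrp - a1a2)^2 / (4 * (rrp - frp)), 0)
  v1v2 <- a1a2 + delay_inc
  a2v2 <- base_avd + delay_inc
  if (jitter_sd > 0) {
    withr_seed(seed)
    v1v2 <- v1v2 + stats::rnorm(length(a1a2), 0, jitter_sd)
  }
  tab <- data.frame(A1A2 = a1a2, V1V2 = v1v2, H1H2 = v1v2, A2V2 = a2v2)
  attr(tab, "truth") <- list(rrp = rrp, frp_programmed = min(v1v2))
  class(tab) <- c("premature_stim_table", "data.frame")
  tab
}
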