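#' Sinus node recovery time after overdrive pacing
#'
#' SNRT is the interval from the last stimulation spike to the first
#' spontaneous sinus-triggered atrial activation; the rate-corrected cSNRT
#' subtracts the averaged sinus cycle length.
#'
#' @param last_stim_time time of the last pacing stimulus, s.
#' @param first_spontaneous_atrial_time time of the first spontaneous
#'   atrial activation, s.
#' @param mean_scl averaged sinus cycle length, ms (> 0).
#' @return List with `snrt` and `csnrt`, both ms.
#' @export
compute_snrt <- function(last_stim_time, first_spontaneous_atrial_time,
                         mean_scl) {
  if (mean_scl <= 0) stop("'mean_scl' must be > 0")
  if (first_spontaneous_atrial_time <= last_stim_time) {
    stop("first spontaneous activation must follow the last stimulus")
  }
  snrt <- (first_spontaneous_atrial_time - last_stim_time) * 1000
  list(snrt = snrt, csnrt = snrt - mean_scl)
}

#' Sinoatrial conduction time from premature atrial stimulation
#'
#' Rows whose return cycle satisfies the fully compensatory identity
#' `|A1A2 + A2A3 - 2 A1A1| <= epsilon` are labelled `compensatory`.
#' Scanning the coupling intervals in descending order, the first row
#' deviating beyond `epsilon` with `A2A3 > A1A1` marks the onset of the
#' reset zone; SACT is `(A2A3 - A1A1)/2` there (`method = "first"`) or the
#' mean of that quantity over the whole reset plateau
#' (`method = "plateau"`). To guard against isolated measurement outliers
#' the deviating row must be followed by another deviating row (or be the
#' shortest coupling tested).
#'
#' @param table a `premature_stim_table` (or data frame) with columns
#'   `A1A1`, `A1A2`, `A2A3`.
#' @param epsilon tolerance of the compensatory-line test, ms.
#' @param method `"first"` uses the first deviating row, `"plateau"` the
#'   reset-plateau mean.
#' @return An object of class `sact_result`: `sact` (ms), `reset_onset`
#'   (ms, A1A2 at the detected onset), `zones` (per-row labels),
#'   `automaticity_ratio` (mean A3A4 / mean A1A1, when A3A4 present).
#' @export
compute_sact <- function(table, epsilon = 5,
                         method = c("first", "plateau")) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  stopifnot(all(c("A1A1", "A1A2", "A2A3") %in% names(table)))
  if ("captured" %in% names(table)) {
    table <- table[table$captured %in% TRUE, , drop = FALSE]
  }
  table <- table[stats::complete.cases(table[c("A1A1", "A1A2", "A2A3")]), ,
                 drop = FALSE]
  if (!nrow(table)) stop("no captured rows in the table")
  o <- order(table$A1A2, decreasing = TRUE)
  tab <- table[o, , drop = FALSE]
  dev <- tab$A1A2 + tab$A2A3 - 2 * tab$A1A1
  deviates <- abs(dev) > epsilon & tab$A2A3 > tab$A1A1

  onset_i <- NA_integer_
  for (j in seq_along(deviates)) {
    if (!deviates[j]) next
    if (j == length(deviates) || deviates[j + 1L]) { onset_i <- j; break }
  }
  if (all(!deviates)) stop("no reset zone observed: all rows compensatory")
  if (is.na(onset_i)) stop("no consistent reset zone observed")
  if (onset_i == 1L) {
    stop("no compensatory zone: all rows deviate from the diagonal")
  }

  zones <- rep("compensatory", nrow(tab))
  zones[onset_i:nrow(tab)] <- "reset"
  half_ct <- (tab$A2A3 - tab$A1A1) / 2
  sact <- switch(method,
                 first = half_ct[onset_i],
                 plateau = mean(half_ct[zones == "reset"]))
  ratio <- if ("A3A4" %in% names(tab)) {
    mean(tab$A3A4) / mean(tab$A1A1)
  } else NA_real_
  structure(
    list(sact = sact, reset_onset = tab$A1A2[onset_i],
         zones = zones[order(o)], method = method,
         automaticity_ratio = ratio),
    class = "sact_result")
}

#' @export
print.sact_result <- function(x, ...) {
  cat(sprintf("sact_result: SACT %.2f ms (reset onset at A1A2 %.1f ms, %s)\n",
              x$sact, x$reset_onset, x$method))
  if (is.finite(x$automaticity_ratio)) {
    cat(sprintf("  automaticity ratio A3A4/A1A1 = %.3f\n",
                x$automaticity_ratio))
  }
  invisible(x)
}

#' AV conduction and latency curves from premature stimulation
#'
#' The functional refractory period (FRP) of the AV conduction system is
#' the shortest V1V2 interval. The conduction curve plots V1V2 against
#' A1A2, the latency curve A2V2 against A1A2. Rows where H1H2 departs from
#' V1V2 beyond `hv_tolerance` are flagged (delay accruing below the His
#' bundle rather than in the AV node).
#'
#' @param table data frame with columns `A1A2`, `V1V2` and optionally
#'   `H1H2`, `A2V2`.
#' @param hv_tolerance tolerated |V1V2 - H1H2| difference, ms.
#' @return An object of class `av_curves`: `frp` (ms), `curve`
#'   (A1A2-sorted conduction points), `latency`, `hv_mismatch` (row flags).
#' @export
av_conduction_curves <- function(table, hv_tolerance = 2) {
  table <- as.data.frame(table)
  stopifnot(all(c("A1A2", "V1V2") %in% names(table)))
  if (!nrow(table)) stop("empty premature-stimulation table")
  o <- order(table$A1A2)
  curve <- data.frame(A1A2 = table$A1A2[o], V1V2 = table$V1V2[o])
  latency <- if ("A2V2" %in% names(table)) {
    data.frame(A1A2 = table$A1A2[o], A2V2 = table$A2V2[o])
  } else NULL
  mism <- if ("H1H2" %in% names(table)) {
    abs(table$V1V2 - table$H1H2)[o] > hv_tolerance
  } else rep(NA, nrow(table))
  structure(
    list(frp = min(table$V1V2), curve = curve, latency = latency,
         hv_mismatch = mism),
    class = "av_curves")
}

#' @export
print.av_curves <- function(x, ...) {
  cat(sprintf("av_curves: FRP %.1f ms over %d couplings\n",
              x$frp, nrow(x$curve)))
  if (any(x$hv_mismatch %in% TRUE)) {
    cat("  note:", sum(x$hv_mismatch %in% TRUE),
        "row(s) with H1H2 departing from V1V2\n")
  }
  invisible(x)
}

#' Effective refractory period from an S1S2 conduction table
#'
#' ERP is the longest S1S2 pacing interval with loss of conduction.
#'
#' @param table data frame with columns `S1S2` (ms) and `conducted`
#'   (logical).
#' @return ERP in ms.
#' @export
find_erp <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("S1S2", "conducted") %in% names(table)))
  lost <- table$S1S2[!table$conducted]
  if (!length(lost)) stop("ERP not reached: all intervals conducted")
  max(lost)
}
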