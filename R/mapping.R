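#' Activation-time map from a fluorescence frame stack
#'
#' Each pixel's signal is background-subtracted, amplitude-normalized and
#' (for voltage-dye polarity) inverted so upstrokes point upward; the
#' activation time is the midpoint of the frame step with the maximum
#' temporal derivative. Times are referenced to the earliest valid pixel
#' (the leading pacemaker site), which is therefore 0. Pixels without a
#' clear upstroke (relative amplitude below `min_amplitude`) are removed
#' from the mask.
#'
#' @param stack a [frame_stack()].
#' @param mask optional logical matrix of pixels to analyse.
#' @param invert invert the fluorescence polarity (TRUE for voltage dyes
#'   whose emission falls on depolarisation).
#' @param min_amplitude minimum per-pixel amplitude, as a fraction of the
#'   median pixel amplitude, for the pixel to stay in the mask.
#' @param smooth_frames half-width (frames) of a running-mean temporal
#'   smoother applied before differentiation; 0 disables it.
#' @return An object of class `activation_map`: `times_ms` (matrix,
#'   earliest pixel = 0), `mask`, `pitch_um`, `leading_site`
#'   (`c(row, col)` of the earliest pixel), `t_ref_ms` (absolute time of
#'   the earliest pixel within the stack, ms).
#' @export
activation_map <- function(stack, mask = NULL, invert = TRUE,
                           min_amplitude = 0.2, smooth_frames = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  stopifnot(identical(dim(mask), d[1:2]))
  dt_ms <- 1000 / stack$frame_rate_hz

  times <- matrix(NA_real_, d[1L], d[2L])
  amps <- matrix(NA_real_, d[1L], d[2L])
  for (r in seq_len(d[1L])) {
    for (cc in seq_len(d[2L])) {
      if (!mask[r, cc]) next
      s <- stack$frames[r, cc, ]
      if (invert) s <- -s
      if (smooth_frames > 0) s <- smooth_running(s, smooth_frames)
      amps[r, cc] <- max(s) - min(s)
      ds <- diff(s)
      k <- which.max(ds)
      times[r, cc] <- (k - 0.5) * dt_ms
    }
  }
  med_amp <- stats::median(amps[mask], na.rm = TRUE)
  ok <- mask & !is.na(amps) & amps >= min_amplitude * med_amp
  times[!ok] <- NA_real_
  if (!any(ok)) stop("no pixel shows an upstroke")
  t0 <- min(times[ok])
  times <- times - t0
  lead <- which(times == 0 & ok, arr.ind = TRUE)[1L, ]
  structure(
    list(times_ms = times, mask = ok, pitch_um = stack$pitch_um,
         leading_site = as.integer(lead), t_ref_ms = t0),
    class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "activation_map: %d x %d pixels, %d valid; leading site (%d, %d)\n",
    nrow(x$times_ms), ncol(x$times_ms), sum(x$mask),
    x$leading_site[1L], x$leading_site[2L]))
  cat(sprintf("  activation spread %.2f ms\n",
              max(x$times_ms[x$mask]) - min(x$times_ms[x$mask])))
  invisible(x)
}

#' @export
plot.activation_map <- function(x, ...) {
  graphics::image(t(x$times_ms)[, nrow(x$times_ms):1],
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::title("activation time (earliest = 0)")
  invisible(x)
}

#' Optical sinoatrial conduction time between two regions of interest
#'
#' The difference between the earliest activation in the atrial exit ROI
#' (crista terminalis) and the earliest activation in the SAN ROI.
#'
#' @param map an [activation_map()].
#' @param roi_san,roi_ct logical matrices, or two-column (row, col) index
#'   matrices, selecting the SAN and crista terminalis pixels.
#' @return SACT in ms.
#' @export
optical_sact <- function(map, roi_san, roi_ct) {
  stopifnot(inherits(map, "activation_map"))
  earliest <- function(roi, label) {
    sel <- if (is.logical(roi)) {
      stopifnot(identical(dim(roi), dim(map$times_ms)))
      roi & map$mask
    } else {
      m <- matrix(FALSE, nrow(map$times_ms), ncol(map$times_ms))
      m[as.matrix(roi)] <- TRUE
      m & map$mask
    }
    if (!any(sel)) stop("ROI '", label, "' contains no valid pixel")
    min(map$times_ms[sel])
  }
  earliest(roi_ct, "ct") - earliest(roi_san, "san")
}

#' Normalized pacemaker shift
#'
#' Euclidean distance between two leading-pacemaker sites, converted to
#' micrometres by the pixel pitch and normalized to the preparation size.
#'
#' @param site_a,site_b `c(row, col)` pixel coordinates.
#' @param pitch_um pixel pitch, micrometres.
#' @param preparation_extent_um preparation size, micrometres (> 0).
#' @return Dimensionless normalized shift.
#' @export
pacemaker_shift <- function(site_a, site_b, pitch_um,
                            preparation_extent_um) {
  if (preparation_extent_um <= 0) stop("'preparation_extent_um' must be > 0")
  d_px <- sqrt(sum((as.numeric(site_a) - as.numeric(site_b))^2))
  d_px * pitch_um / preparation_extent_um
}

#' Normalized fluorescence change of a calcium signal
#'
#' After background subtraction, the baseline fluorescence F0 is the mean
#' over the baseline window; the result is `(F - background - F0) / F0`.
#'
#' @param roi_trace a [uniform_trace()] of raw ROI fluorescence (a.u.).
#' @param background background fluorescence level, a.u.
#' @param baseline_window `c(from, to)` in seconds, preceding the events.
#' @return An object of class `dff_result`: `trace` (a [uniform_trace()]
#'   of dF/F0), `f0`, `background`.
#' @export
dff <- function(roi_trace, background, baseline_window) {
  stopifnot(inherits(roi_trace, "uniform_trace"))
  tt <- trace_times(roi_trace)
  base <- roi_trace$values[tt >= baseline_window[1] &
                             tt <= baseline_window[2]] - background
  if (!length(base)) stop("baseline window contains no samples")
  f0 <- mean(base)
  if (f0 <= 0) stop("baseline fluorescence F0 must be > 0 after ",
                    "background subtraction")
  vals <- (roi_trace$values - background - f0) / f0
  structure(
    list(trace = uniform_trace(vals, roi_trace$sampling_rate,
                               units = "dF/F0", t0 = roi_trace$t0),
         f0 = f0, background = background),
    class = "dff_result")
}

#' @export
print.dff_result <- function(x, ...) {
  cat(sprintf("dff_result: F0 %.4g a.u. (background %.4g); peak dF/F0 %.3f\n",
              x$f0, x$background, max(x$trace$values)))
  invisible(x)
}

#' Density of subthreshold-activity cells
#'
#' @param n_cells number of cells displaying localized diastolic calcium
#'   release.
#' @param area_um2 measured surface area, square micrometres (> 0).
#' @return Cells per square micrometre.
#' @export
subthreshold_density <- function(n_cells, area_um2) {
  if (area_um2 <= 0) stop("'area_um2' must be > 0")
  n_cells / area_um2
}
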