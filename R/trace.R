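#' Uniformly sampled trace
#'
#' Container for an evenly sampled time series, typically a membrane
#' potential (mV) or current (pA) recording. Time of sample `i` is
#' `t0 + (i - 1) / sampling_rate`.
#'
#' @param values numeric vector of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param units unit label of the samples (e.g. `"mV"`, `"pA"`, `"a.u."`).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `uniform_trace`.
#' @export
uniform_trace <- function(values, sampling_rate, units = "mV", t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number (Hz)")
  }
  structure(
    list(values = as.numeric(values),
         sampling_rate = as.numeric(sampling_rate),
         units = as.character(units),
         t0 = as.numeric(t0)),
    class = "uniform_trace"
  )
}

#' @export
print.uniform_trace <- function(x, ...) {
  cat(sprintf("uniform_trace: %d samples at %g Hz (%.3f s), units %s\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate, x$units))
  cat(sprintf("  range: [%.3f, %.3f] %s\n",
              min(x$values), max(x$values), x$units))
  invisible(x)
}

#' @export
length.uniform_trace <- function(x) length(x$values)

#' Sample times of a uniform trace
#'
#' @param trace a [uniform_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$sampling_rate
}

#' Duration of a uniform trace in seconds
#' @param trace a [uniform_trace()].
#' @export
trace_duration <- function(trace) {
  length(trace$values) / trace$sampling_rate
}

#' Extract a time window from a trace
#'
#' @param trace a [uniform_trace()].
#' @param from,to window limits in seconds (same time base as the trace).
#' @return A `uniform_trace` restricted to `[from, to]`.
#' @export
trace_window <- function(trace, from, to) {
  stopifnot(inherits(trace, "uniform_trace"), from < to)
  tt <- trace_times(trace)
  keep <- tt >= from & tt <= to
  if (!any(keep)) stop("window [", from, ", ", to, "] outside trace")
  uniform_trace(trace$values[keep], trace$sampling_rate, trace$units,
                t0 = tt[which(keep)[1L]])
}

#' @export
plot.uniform_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = x$units, ...)
  invisible(x)
}

#' Per-beat series
#'
#' A data frame with one row per heart beat: beat index, beat time (s), RR
#' interval (ms) and, optionally, systolic blood pressure (mmHg). Beat time
#' is the time of the beat terminating the RR interval.
#'
#' @param rr_ms RR intervals in milliseconds.
#' @param t_s beat times in seconds; defaults to the cumulative sum of RR.
#' @param sbp_mmhg optional systolic blood pressure per beat, mmHg.
#' @return A data frame of class `beat_series` with columns
#'   `beat`, `t_s`, `rr_ms` and optionally `sbp_mmhg`.
#' @export
beat_series <- function(rr_ms, t_s = NULL, sbp_mmhg = NULL) {
  stopifnot(is.numeric(rr_ms), length(rr_ms) >= 1L)
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("all RR intervals must be finite and > 0")
  }
  if (is.null(t_s)) t_s <- cumsum(rr_ms) / 1000
  stopifnot(length(t_s) == length(rr_ms))
  out <- data.frame(beat = seq_along(rr_ms), t_s = as.numeric(t_s),
                    rr_ms = as.numeric(rr_ms))
  if (!is.null(sbp_mmhg)) {
    stopifnot(length(sbp_mmhg) == length(rr_ms))
    out$sbp_mmhg <- as.numeric(sbp_mmhg)
  }
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Write / read a trace as 2-column delimited text
#'
#' The on-disk dialect is tab-separated `time_s`, `value` with a header line;
#' the sampling rate is recovered from the time column on read.
#'
#' @param trace a [uniform_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "uniform_trace"))
  utils::write.table(
    data.frame(time_s = trace_times(trace), value = trace$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param units unit label to attach on read.
#' @export
read_trace <- function(path, units = "mV") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "value") %in% names(d)), nrow(d) >= 2L)
  dt <- diff(d$time_s)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time column is not uniformly sampled")
  }
  uniform_trace(d$value, sampling_rate = 1 / mean(dt), units = units,
                t0 = d$time_s[1L])
}

#' Write / read a beat table as delimited text
#'
#' Headered tab-separated columns `beat`, `t_s`, `rr_ms` and, when present,
#' `sbp_mmhg`.
#'
#' @param beats a [beat_series()].
#' @param path file path.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  utils::write.table(beats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("beat", "t_s", "rr_ms") %in% names(d)))
  beat_series(d$rr_ms, t_s = d$t_s,
              sbp_mmhg = if ("sbp_mmhg" %in% names(d)) d$sbp_mmhg)
}

#' Fluorescence frame stack
#'
#' A 3-D array (rows x columns x frames) of fluorescence samples with pixel
#' pitch (micrometres) and frame rate (Hz) attached.
#'
#' @param frames numeric 3-D array, `dim = c(nrow, ncol, nframes)`.
#' @param pitch_um pixel pitch in micrometres.
#' @param frame_rate_hz frame rate in Hz.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pitch_um, frame_rate_hz) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            pitch_um > 0, frame_rate_hz > 0)
  structure(list(frames = frames, pitch_um = as.numeric(pitch_um),
                 frame_rate_hz = as.numeric(frame_rate_hz)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frame_stack: %d x %d pixels (%g um pitch) x %d frames at %g Hz\n",
    d[1L], d[2L], x$pitch_um, d[3L], x$frame_rate_hz))
  invisible(x)
}
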