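#' Synthetic steady-state activation dataset
#'
#' Generates tail-current amplitudes on the Boltzmann sigmoid defined by a
#' [channel_preset()] at the requested test potentials, optionally with
#' additive Gaussian noise. With `noise_sd = 0` the points lie exactly on
#' the sigmoid, so [fit_boltzmann()] recovers the preset parameters.
#'
#' @param preset a [channel_preset()].
#' @param test_potentials test potentials, mV; at least 6 values spanning
#'   the curve.
#' @param noise_sd additive noise SD, in the same (typically normalized)
#'   units as the current.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return A data frame with columns `v_m` (mV) and `current`.
#' @export
gen_activation_dataset <- function(preset, test_potentials = seq(-140, -40, 10),
                                   noise_sd = 0, seed = 1) {
  stopifnot(inherits(preset, "channel_preset"))
  if (preset$k <= 0) stop("slope factor 'k' must be > 0")
  if (length(test_potentials) < 6L) {
    stop("need at least 6 test potentials spanning the activation curve")
  }
  i <- boltzmann_curve(test_potentials, preset$v05, preset$k,
                       preset$imin, preset$imax)
  if (noise_sd > 0) {
    withr_seed(seed)
    i <- i + stats::rnorm(length(i), 0, noise_sd)
  }
  data.frame(v_m = as.numeric(test_potentials), current = i)
}

# hyperpolarization-activated sigmoid: current rises towards imax as V_m
# hyperpolarizes, equals (imin + imax)/2 at v05
boltzmann_curve <- function(v_m, v05, k, imin = 0, imax = 1) {
  imin + (imax - imin) / (1 + exp((v_m - v05) / k))
}

#' Synthetic exponential current time course
#'
#' Emits a current trace following `I(t) = Iss + A1 exp(-(t - delay)/tau1)
#' (+ A2 exp(-(t - delay)/tau2))` after the preset's initial delay; before
#' the delay the trace holds the t = delay value of the ideal curve.
#' Amplitudes are taken from the preset: the total amplitude is
#' `imax - imin` split by `a1_frac` between the slow (`tau1`) and fast
#' (`tau2`) components (all of it on `tau1` for `order = 1`), decaying from
#' `imax` down to the steady state `imin`.
#'
#' @param preset a [channel_preset()].
#' @param duration trace duration, s (> 5 * tau1).
#' @param sampling_rate sampling rate, Hz.
#' @param order 1 or 2 exponential components.
#' @param noise_sd additive noise SD, pA.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return A [uniform_trace()] in pA.
#' @export
gen_current_trace <- function(preset, duration = NULL, sampling_rate = 1000,
                              order = 2, noise_sd = 0, seed = 1) {
  stopifnot(inherits(preset, "channel_preset"))
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2")
  if (is.null(duration)) duration <- 6 * preset$tau1 + preset$delay
  if (duration <= 5 * preset$tau1) {
    stop("'duration' must exceed 5 * tau1 for the decay to complete")
  }
  n <- floor(duration * sampling_rate) + 1L
  tt <- (seq_len(n) - 1L) / sampling_rate
  amp <- preset$imax - preset$imin
  if (order == 1) {
    a1 <- amp; a2 <- 0
  } else {
    a1 <- amp * preset$a1_frac; a2 <- amp * (1 - preset$a1_frac)
  }
  s <- pmax(tt - preset$delay, 0)
  v <- preset$imin + a1 * exp(-s / preset$tau1) + a2 * exp(-s / preset$tau2)
  if (noise_sd > 0) {
    withr_seed(seed)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  out <- uniform_trace(v, sampling_rate, units = "pA")
  out$events <- list(preset = preset, order = order,
                     amplitudes = c(a1, a2)[seq_len(order)])
  out
}
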