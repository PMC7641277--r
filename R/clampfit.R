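#' Fit a Boltzmann steady-state activation curve
#'
#' Least-squares fit of the hyperpolarization-activated sigmoid
#' `I(V) = imin + (imax - imin) / (1 + exp((V - v05)/k))` to tail-current
#' measurements, so that `v05` is the membrane potential of half-maximal
#' activation and `k` (> 0) the slope factor. With `normalize = TRUE` the
#' currents are first scaled by the maximum current, the protocol's usual
#' normalization.
#'
#' @param points a data frame with columns `v_m` (test potential, mV) and
#'   `current` (tail current), or any two-column table in that order.
#' @param normalize scale currents by the maximum current before fitting.
#' @return An object of class `boltzmann_fit` with elements `v05`, `k`,
#'   `imin`, `imax`, `rss`, `n_points`, `fitted`, `data`.
#' @examples
#' d <- gen_activation_dataset(hcn_presets("wt_camp_hp55"))
#' fit_boltzmann(d)
#' @export
fit_boltzmann <- function(points, normalize = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("v_m", "current") %in% names(points))) {
    stopifnot(ncol(points) >= 2L)
    names(points)[1:2] <- c("v_m", "current")
  }
  v <- as.numeric(points$v_m)
  i <- as.numeric(points$current)
  if (any(!is.finite(v)) || any(!is.finite(i))) {
    stop("voltages and currents must all be finite")
  }
  if (length(unique(v)) < 5L) {
    stop("need at least 5 distinct test potentials")
  }
  if (normalize) {
    scale <- max(abs(i))
    if (scale == 0) stop("no sigmoid structure: all currents are zero")
    i <- i / scale
  }
  rng <- diff(range(i))
  if (rng <= 1e-12 * max(1, max(abs(i)))) {
    stop("no sigmoid structure: currents are flat across the voltage range")
  }

  ord <- order(v)
  vs <- v[ord]; is <- i[ord]
  mid <- (max(i) + min(i)) / 2
  # first crossing of the half-range level, linearly interpolated
  above <- is >= mid
  cross <- which(diff(above) != 0)
  v05_0 <- if (length(cross)) {
    j <- cross[1L]
    vs[j] + (mid - is[j]) * (vs[j + 1L] - vs[j]) / (is[j + 1L] - is[j])
  } else stats::median(vs)

  dat <- data.frame(v = v, i = i)
  # minpack is sensitive to the exact starting point; try a small ladder of
  # starts and keep the first converged fit
  starts <- list(
    c(v05_0, 10), c(stats::median(vs), 10), c(v05_0 - 5, 8),
    c(v05_0 + 5, 12), c(v05_0, 15))
  fit <- NULL
  last_err <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        i ~ imin + (imax - imin) / (1 + exp((v - v05) / k)),
        data = dat,
        start = list(v05 = s0[1], k = s0[2], imin = min(i), imax = max(i)),
        lower = c(v05 = -Inf, k = 1e-3, imin = -Inf, imax = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    last_err <- fit
    fit <- NULL
  }
  if (is.null(fit)) {
    stop("Boltzmann fit did not converge: ", conditionMessage(last_err),
         " (current range ", signif(rng, 4), ", n = ", length(v), ")")
  }
  cf <- stats::coef(fit)
  if (cf[["imin"]] >= cf[["imax"]]) {
    # refit orientation: swap plateaus via the k sign convention is not
    # allowed (k > 0), so a fit landing upside down means no sigmoid
    stop("no sigmoid structure: fitted plateaus are inverted")
  }
  res <- stats::resid(fit)
  v05 <- cf[["v05"]]
  if (v05 < min(v) - 20 || v05 > max(v) + 20) {
    warning("fitted v05 (", round(v05, 1),
            " mV) lies outside the sampled range +/- 20 mV")
  }
  structure(
    list(v05 = v05, k = cf[["k"]], imin = cf[["imin"]],
         imax = cf[["imax"]], rss = sum(res^2), n_points = length(v),
         fitted = stats::fitted(fit), data = dat),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann activation fit\n")
  cat(sprintf("  v05 = %.2f mV, k = %.2f mV\n", x$v05, x$k))
  cat(sprintf("  plateaus: imin = %.4g, imax = %.4g\n", x$imin, x$imax))
  cat(sprintf("  rss = %.4g on %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v05 = object$v05, k = object$k, imin = object$imin, imax = object$imax)
}

#' @export
predict.boltzmann_fit <- function(object, v_m = NULL, ...) {
  if (is.null(v_m)) return(object$fitted)
  boltzmann_curve(v_m, object$v05, object$k, object$imin, object$imax)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$v, x$data$i, xlab = "V_m (mV)", ylab = "current",
                 ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  invisible(x)
}

#' Fit exponential current kinetics
#'
#' Least-squares fit of `I(t) = Iss + A1 exp(-(t - d)/tau1)
#' (+ A2 exp(-(t - d)/tau2))` to a current trace after an initial delay
#' `d`. When `delay` is not supplied it is estimated as the time at which
#' 10% of the total amplitude change has occurred; samples before the delay
#' are excluded from the fit. A second-order fit collapsing onto a single
#' time constant is flagged `degenerate` in the result rather than raising
#' an error.
#'
#' @param trace a [uniform_trace()] (current, pA).
#' @param order 1 or 2 exponential components.
#' @param fit_window optional `c(from, to)` window in seconds.
#' @param delay optional fixed delay, s, overriding the estimate.
#' @return An object of class `exp_fit` with elements `iss`, `amplitudes`,
#'   `taus` (sorted `tau1 >= tau2`), `delay`, `rss`, `degenerate`.
#' @export
fit_exponential <- function(trace, order = 1, fit_window = NULL,
                            delay = NULL) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2")
  if (!is.null(fit_window)) {
    trace <- trace_window(trace, fit_window[1], fit_window[2])
  }
  tt <- trace_times(trace)
  v <- trace$values
  n <- length(v)
  if (n < 10L) stop("trace too short to fit")

  tail_n <- max(5L, floor(0.05 * n))
  iss0 <- mean(v[(n - tail_n + 1L):n])
  total <- v[1L] - iss0
  if (abs(total) < 1e-8 * max(1, abs(v[1L])) || stats::sd(v) < 1e-12) {
    stop("no exponential decay: trace amplitude is flat")
  }
  if (is.null(delay)) {
    past <- abs(v - v[1L]) >= 0.1 * abs(total)
    delay <- if (any(past)) tt[which(past)[1L]] else tt[1L]
  }
  # samples after the delay enter the fit; time is referenced to the start
  # of the analysed stretch, so amplitudes refer to t = 0 of the window
  keep <- tt >= delay
  t0 <- tt[keep] - tt[1L]
  y <- v[keep]
  if (length(y) < 8L) stop("fewer than 8 samples after the delay")

  amp0 <- y[1L] - iss0
  # crude tau from the 1/e crossing of the remaining amplitude
  dec <- abs(y - iss0) <= abs(amp0) / exp(1)
  tau0 <- if (any(dec)) max(t0[which(dec)[1L]], t0[2L]) else max(t0) / 3
  dat <- data.frame(t = t0, y = y)

  fit <- NULL
  if (order == 1) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ iss + A * exp(-t / tau), data = dat,
                        start = list(iss = iss0, A = amp0, tau = tau0),
                        lower = c(iss = -Inf, A = -Inf, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("exponential fit did not converge: ", conditionMessage(fit))
    }
    cf <- stats::coef(fit)
    taus <- cf[["tau"]]; amps <- cf[["A"]]; iss <- cf[["iss"]]
    degenerate <- FALSE
  } else {
    starts <- list(c(2, 0.2), c(3, 0.5), c(1.5, 0.1), c(1, 1))
    fit <- NULL
    last_err <- NULL
    for (s0 in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ iss + A1 * exp(-t / tau1) + A2 * exp(-t / tau2), data = dat,
          start = list(iss = iss0, A1 = 0.6 * amp0, A2 = 0.4 * amp0,
                       tau1 = tau0 * s0[1], tau2 = tau0 * s0[2]),
          lower = c(iss = -Inf, A1 = -Inf, A2 = -Inf,
                    tau1 = 1e-9, tau2 = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 1000)),
        error = function(e) e)
      if (!inherits(fit, "error")) break
      last_err <- fit
      fit <- NULL
    }
    if (is.null(fit)) {
      stop("exponential fit did not converge: ", conditionMessage(last_err))
    }
    cf <- stats::coef(fit)
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    amps <- c(cf[["A1"]], cf[["A2"]])
    if (taus[1L] < taus[2L]) {     # convention: tau1 >= tau2
      taus <- rev(taus); amps <- rev(amps)
    }
    iss <- cf[["iss"]]
    degenerate <- (taus[1L] - taus[2L]) / taus[1L] < 0.05
  }
  res <- stats::resid(fit)
  structure(
    list(iss = iss, amplitudes = amps, taus = taus, delay = delay,
         rss = sum(res^2), degenerate = degenerate, order = order),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-exponential fit (delay %.4g s)\n", x$order, x$delay))
  cat(sprintf("  iss = %.4g\n", x$iss))
  for (j in seq_along(x$taus)) {
    cat(sprintf("  A%d = %.4g, tau%d = %.4g s\n",
                j, x$amplitudes[j], j, x$taus[j]))
  }
  if (isTRUE(x$degenerate)) {
    cat("  note: time constants are degenerate (tau2 ~ tau1)\n")
  }
  cat(sprintf("  rss = %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  out <- c(iss = object$iss)
  for (j in seq_along(object$taus)) {
    out[paste0("A", j)] <- object$amplitudes[j]
    out[paste0("tau", j)] <- object$taus[j]
  }
  out
}

#' Current density from steady-state current and cell capacitance
#'
#' @param steady_current steady-state current amplitude, pA (sign kept).
#' @param capacitance cell capacitance, pF (> 0).
#' @return Current density, pA/pF.
#' @export
current_density <- function(steady_current, capacitance) {
  if (any(capacitance <= 0)) stop("'capacitance' must be > 0")
  steady_current / capacitance
}

#' T-type calcium current by decomposition
#'
#' The T-type component is the peak total calcium current minus the peak
#' L-type current measured with the T-type component inactivated:
#' `i_t = i_tl_peak - i_l_peak` (inward currents negative).
#'
#' @param i_tl_peak peak of the combined T+L current, pA/pF.
#' @param i_l_peak peak of the isolated L-type current, pA/pF.
#' @return T-type peak current density, pA/pF.
#' @export
ica_decompose <- function(i_tl_peak, i_l_peak) {
  if (any(i_tl_peak > 0) || any(i_l_peak > 0)) {
    warning("inward calcium currents are conventionally <= 0")
  }
  i_tl_peak - i_l_peak
}
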