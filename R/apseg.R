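#' Detect action potentials in a pacemaker recording
#'
#' Events are placed at the sample of maximum upstroke velocity. A candidate
#' upstroke must cross the amplitude gate midway between the most negative
#' and most positive potentials of the trace, and a refractory guard
#' suppresses double counting. A flat trace yields an empty result.
#'
#' @param trace a [uniform_trace()] membrane-potential recording sampled at
#'   1 kHz or faster.
#' @param refractory_s refractory guard between events, s.
#' @param min_amplitude minimal peak-to-trough amplitude (mV) for the trace
#'   to be considered to contain action potentials at all.
#' @return Numeric vector of AP times (s), strictly increasing.
#' @export
detect_aps <- function(trace, refractory_s = 0.03, min_amplitude = 20) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (trace$sampling_rate < 1000) stop("sampling rate must be >= 1 kHz")
  v <- trace$values
  if (diff(range(v)) < min_amplitude) return(numeric(0))
  fs <- trace$sampling_rate
  gate <- (max(v) + min(v)) / 2
  up <- which(v[-length(v)] < gate & v[-1L] >= gate)
  if (!length(up)) return(numeric(0))
  dv <- c(diff(v), 0) * fs
  win <- max(1L, round(0.01 * fs))       # search 10 ms around the crossing
  times <- numeric(0)
  last <- -Inf
  tt0 <- trace$t0
  for (j in up) {
    if ((j - 1) / fs + tt0 - last < refractory_s) next
    lo <- max(1L, j - win)
    hi <- min(length(v) - 1L, j + win)
    k <- lo + which.max(dv[lo:hi]) - 1L
    t_ap <- tt0 + (k - 1L) / fs
    if (t_ap - last < refractory_s) next
    times <- c(times, t_ap)
    last <- t_ap
  }
  times
}

#' Per-cycle action-potential features
#'
#' Firing rate, per-cycle maximum diastolic potential (MDP), slope of the
#' slow diastolic depolarisation (SDD) and an upstroke-aligned averaged AP,
#' computed from cycles inside constant-firing stretches (inter-AP
#' intervals up to twice the median interval).
#'
#' The SDD window runs from the MDP to the takeoff point where the smoothed
#' dV/dt first exceeds three times the median diastolic dV/dt; the slope is
#' a linear fit over that window.
#'
#' @param trace a [uniform_trace()].
#' @param ap_times AP times from [detect_aps()]; detected if missing.
#' @return An object of class `ap_features`: `ap_times`,
#'   `firing_rate` (AP/s), `firing_rate_min` (AP/min), `mdp_per_cycle`,
#'   `mdp` (mean, mV), `sdd_slope` (mV/s), `averaged_ap`.
#' @export
ap_features <- function(trace, ap_times = NULL) {
  stopifnot(inherits(trace, "uniform_trace"))
  if (is.null(ap_times)) ap_times <- detect_aps(trace)
  if (length(ap_times) < 3L) stop("insufficient APs (need at least 3)")
  fs <- trace$sampling_rate
  v <- trace$values
  iv <- diff(ap_times)
  thr <- 2 * stats::median(iv)
  firing <- iv <= thr
  if (sum(firing) < 2L) stop("insufficient APs in constant-firing episodes")
  rate <- 1 / mean(iv[firing])

  idx_of <- function(t) pmin(length(v), pmax(1L, round((t - trace$t0) * fs) + 1L))
  vsm <- smooth_running(v, max(1L, round(0.005 * fs)))

  mdp <- numeric(0)
  slopes <- numeric(0)
  for (j in which(firing)) {
    i0 <- idx_of(ap_times[j]); i1 <- idx_of(ap_times[j + 1L])
    if (i1 - i0 < 10L) next
    seg <- vsm[i0:i1]
    im <- i0 + which.min(seg) - 1L               # MDP sample
    mdp <- c(mdp, v[im])
    dia <- vsm[im:i1]
    if (length(dia) > 10L) {
      dvd <- diff(dia) * fs
      med <- stats::median(dvd)
      take <- which(dvd > 3 * max(med, 1e-9))
      i_take <- if (length(take)) im + take[1L] - 1L else i1
      if (i_take - im >= 5L) {
        xs <- (im:i_take - im) / fs
        slopes <- c(slopes, stats::coef(stats::lm(v[im:i_take] ~ xs))[[2L]])
      }
    }
  }

  # upstroke-aligned average over a window of the median cycle
  pre <- round(0.25 * stats::median(iv[firing]) * fs)
  post <- round(0.6 * stats::median(iv[firing]) * fs)
  keep <- which(firing)
  mat <- NULL
  for (j in keep) {
    ic <- idx_of(ap_times[j])
    if (ic - pre < 1L || ic + post > length(v)) next
    mat <- rbind(mat, v[(ic - pre):(ic + post)])
  }
  avg <- if (!is.null(mat)) {
    uniform_trace(colMeans(mat), fs, units = trace$units,
                  t0 = -pre / fs)
  } else NULL

  structure(
    list(ap_times = ap_times, firing_rate = rate,
         firing_rate_min = 60 * rate, mdp_per_cycle = mdp,
         mdp = mean(mdp), sdd_slope = mean(slopes),
         averaged_ap = avg),
    class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("ap_features: %d APs, %.1f AP/min (%.2f AP/s)\n",
              length(x$ap_times), x$firing_rate_min, x$firing_rate))
  cat(sprintf("  MDP %.2f mV, SDD slope %.1f mV/s\n", x$mdp, x$sdd_slope))
  invisible(x)
}

#' Segment a pacemaker recording into firing and nonfiring modes
#'
#' Silent gaps of at least `min_episode` seconds whose mean potential lies
#' within `mdp_gate` mV of the trace's average firing-cycle MDP become
#' nonfiring episodes; all remaining time is firing. The cell is classed
#' `episodic` if any nonfiring episode reaches `class_threshold` seconds,
#' `permanent` otherwise. Per-episode depolarisation `delta_vm` is the
#' magnitude of the potential difference between episode termination
#' (100 ms before the next takeoff) and onset (100 ms after the last AP's
#' repolarisation ends). Episodes truncated by the recording window are
#' flagged `edge`: they count towards the percentage of nonfiring time but
#' are excluded from duration and `delta_vm` statistics.
#'
#' @param trace a [uniform_trace()] of at least 30 s.
#' @param ap_times AP times from [detect_aps()]; detected if missing.
#' @param min_episode shortest nonfiring episode entering statistics, s.
#' @param class_threshold episode duration defining an episodic cell, s.
#' @param mdp_gate potential gate around the average MDP, mV.
#' @return An object of class `episode_segmentation`: `episodes` (data
#'   frame `start`, `end`, `mode`, `edge` tiling the trace), `delta_vm`
#'   (per interior nonfiring episode, mV), `nonfiring_durations` (s),
#'   `pct_nonfiring`, `cell_class`, `avg_mdp`.
#' @export
segment_modes <- function(trace, ap_times = NULL, min_episode = 3.5,
                          class_threshold = 10, mdp_gate = 10) {
  stopifnot(inherits(trace, "uniform_trace"))
  dur <- trace_duration(trace)
  if (dur < 30) stop("trace must be at least 30 s for classification")
  if (is.null(ap_times)) ap_times <- detect_aps(trace)
  if (!length(ap_times)) stop("no firing detected")
  fs <- trace$sampling_rate
  v <- trace$values
  t0 <- trace$t0
  t_end <- t0 + dur
  vsm <- smooth_running(v, max(1L, round(0.015 * fs)))
  idx_of <- function(t) pmin(length(v), pmax(1L, round((t - t0) * fs) + 1L))

  # average MDP over firing cycles (inter-AP intervals below the episode
  # floor are within-bout by construction)
  iv <- diff(ap_times)
  cyc <- which(iv < min_episode)
  if (length(cyc)) {
    mdps <- vapply(cyc, function(j) {
      min(vsm[idx_of(ap_times[j]):idx_of(ap_times[j + 1L])])
    }, numeric(1))
    avg_mdp <- mean(mdps)
  } else {
    avg_mdp <- min(vsm)
  }

  # end of an AP's repolarisation: first non-negative smoothed slope after
  # the post-AP downstroke, searched within 500 ms
  repol_end <- function(t_ap) {
    i0 <- idx_of(t_ap) + max(1L, round(0.005 * fs))
    i1 <- min(length(v), idx_of(t_ap) + round(0.5 * fs))
    if (i1 - i0 < 5L) return(t_ap + 0.1)
    dv <- diff(vsm[i0:i1])
    neg <- which(dv < 0)
    if (!length(neg)) return(t_ap + 0.1)
    pos <- which(dv[-seq_len(neg[1L])] >= 0)
    if (!length(pos)) return(t_ap + 0.1)
    t0 + (i0 + neg[1L] + pos[1L] - 2L) / fs
  }

  win_mean <- function(t) {
    i <- idx_of(t)
    w <- round(0.02 * fs)
    mean(v[max(1L, i - w):min(length(v), i + w)])
  }

  ep_start <- numeric(0); ep_end <- numeric(0); ep_edge <- logical(0)
  dvm <- numeric(0)

  consider <- function(s, e, edge) {
    if (e - s < min_episode) return(invisible(NULL))
    m <- mean(v[idx_of(s):idx_of(e)])
    if (abs(m - avg_mdp) > mdp_gate) return(invisible(NULL))
    ep_start <<- c(ep_start, s); ep_end <<- c(ep_end, e)
    ep_edge <<- c(ep_edge, edge)
    if (!edge) dvm <<- c(dvm, abs(win_mean(e - 0.1) - win_mean(s + 0.1)))
    invisible(NULL)
  }

  # interior gaps
  long <- which(iv >= min_episode)
  for (j in long) {
    s <- repol_end(ap_times[j])
    e <- ap_times[j + 1L] - 0.002
    consider(s, e, edge = FALSE)
  }
  # edges
  consider(t0, ap_times[1L] - 0.002, edge = TRUE)
  if (length(ap_times) >= 1L) {
    s <- repol_end(ap_times[length(ap_times)])
    if (t_end - s >= min_episode) consider(s, t_end, edge = TRUE)
  }

  o <- order(ep_start)
  ep_start <- ep_start[o]; ep_end <- ep_end[o]; ep_edge <- ep_edge[o]

  # tile the trace: firing fills the complement
  bounds <- sort(unique(c(t0, t_end, ep_start, ep_end)))
  episodes <- data.frame(start = bounds[-length(bounds)],
                         end = bounds[-1L])
  episodes$mode <- "firing"
  episodes$edge <- FALSE
  for (j in seq_along(ep_start)) {
    hit <- episodes$start >= ep_start[j] - 1e-9 &
      episodes$end <= ep_end[j] + 1e-9
    episodes$mode[hit] <- "nonfiring"
    episodes$edge[hit] <- ep_edge[j]
  }

  nf_total <- sum(ep_end - ep_start)
  durations <- (ep_end - ep_start)[!ep_edge]
  cell_class <- if (length(ep_end) &&
                    any(ep_end - ep_start >= class_threshold)) {
    "episodic"
  } else "permanent"

  structure(
    list(episodes = episodes, delta_vm = dvm,
         nonfiring_durations = durations,
         pct_nonfiring = 100 * nf_total / dur,
         cell_class = cell_class, avg_mdp = avg_mdp,
         duration = dur),
    class = "episode_segmentation")
}

#' @export
print.episode_segmentation <- function(x, ...) {
  n_nf <- sum(x$episodes$mode == "nonfiring")
  cat(sprintf("episode_segmentation: %s cell, %.1f%% nonfiring\n",
              x$cell_class, x$pct_nonfiring))
  cat(sprintf("  %d nonfiring episode(s); interior durations: %s s\n",
              n_nf, paste(round(x$nonfiring_durations, 1), collapse = ", ")))
  if (length(x$delta_vm)) {
    cat(sprintf("  delta Vm: %s mV\n",
                paste(round(x$delta_vm, 2), collapse = ", ")))
  }
  invisible(x)
}

#' Cumulative dose-response as percentage reduction of firing rate
#'
#' @param rates data frame with columns `concentration` and `firing_rate`.
#' @param basal basal firing rate (> 0) used for normalization.
#' @return Data frame `concentration`, `firing_rate`, `pct_reduction`
#'   ordered by concentration.
#' @export
dose_response <- function(rates, basal) {
  rates <- as.data.frame(rates)
  stopifnot(all(c("concentration", "firing_rate") %in% names(rates)))
  if (length(basal) != 1L || basal <= 0) stop("'basal' must be > 0")
  out <- rates[order(rates$concentration), , drop = FALSE]
  out$pct_reduction <- 100 * (1 - out$firing_rate / basal)
  rownames(out) <- NULL
  out
}

# centred running mean; width is the half-window in samples
smooth_running <- function(x, half) {
  if (half <= 0L) return(x)
  k <- 2L * half + 1L
  f <- stats::filter(x, rep(1 / k, k), sides = 2)
  f <- as.numeric(f)
  f[seq_len(half)] <- f[half + 1L]
  n <- length(x)
  f[(n - half + 1L):n] <- f[n - half]
  f
}
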