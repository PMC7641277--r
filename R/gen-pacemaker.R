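#' Synthetic sinoatrial pacemaker-cell recording
#'
#' Emits a membrane-potential trace that alternates firing bouts (stylized
#' action potentials whose maximum diastolic potential drifts from
#' `mdp_onset` towards `mdp_end`) with nonfiring episodes (a smooth
#' half-cosine depolarisation by `delta_vm`). Episode durations are drawn
#' from a truncated normal floored at 3.5 s; the alternating renewal process
#' is started in its stationary regime (length-biased first interval) so the
#' expected fraction of silent time equals `frac_nonfiring` over any window.
#'
#' The returned trace carries the generator's event log in `$events`:
#' `ap_times` (upstroke times, s), and `episodes`, a data frame of silent
#' episodes with programmed onset/termination times, potentials, and an
#' `edge` flag for episodes truncated by the recording window.
#'
#' @param preset a [pacemaker_preset()].
#' @param duration trace duration, s; must cover at least one firing cycle.
#' @param sampling_rate sampling rate, Hz (>= 1000).
#' @param seed integer seed; all randomness derives from it.
#' @return A [uniform_trace()] (mV) with an `$events` log.
#' @export
gen_pacemaker_trace <- function(preset, duration, sampling_rate = 1000,
                                seed = 1) {
  stopifnot(inherits(preset, "pacemaker_preset"))
  if (sampling_rate < 1000) stop("'sampling_rate' must be >= 1 kHz")
  period <- 1 / preset$firing_rate
  if (duration < period) {
    stop("'duration' too short to contain one action potential cycle")
  }
  if (preset$frac_nonfiring >= 1) stop("'frac_nonfiring' must be < 1")

  d1 <- (preset$takeoff - preset$mdp_onset) / preset$sdd_slope
  d2 <- preset$upstroke_s
  d3 <- period - d1 - d2
  if (d3 <= 0) stop("waveform inconsistent: SDD + upstroke exceed the period")

  f <- preset$frac_nonfiring
  withr_seed(seed)

  if (f > 0) {
    s_mean_real <- truncnorm_mean(preset$mean_episode_s, preset$episode_sd_s,
                                  3.5)
    bout_floor <- max(2, 3 * period)
    cv <- if (preset$mean_episode_s > 0) {
      preset$episode_sd_s / preset$mean_episode_s
    } else 0.3
    bout_target <- s_mean_real * (1 - f) / f
    bout_sd <- cv * bout_target
    bout_mu <- solve_truncnorm_mu(bout_target, bout_sd, bout_floor)
    drift_rate <- (preset$mdp_end - preset$mdp_onset) / bout_target
  } else {
    drift_rate <- 0
  }

  rand_silent <- function() rtruncnorm1(preset$mean_episode_s,
                                        preset$episode_sd_s, 3.5)
  rand_bout <- function() rtruncnorm1(bout_mu, bout_sd, bout_floor)

  # --- build the continuous-time segment schedule -------------------------
  segs <- list()          # each: list(t0, t1, type, a, b) -- see eval below
  ap_times <- numeric(0)
  ep_start <- numeric(0); ep_end <- numeric(0)
  ep_v0 <- numeric(0); ep_v1 <- numeric(0)

  add_seg <- function(t0, t1, type, a, b) {
    segs[[length(segs) + 1L]] <<- list(t0 = t0, t1 = t1, type = type,
                                       a = a, b = b)
  }

  # one firing cycle starting at an MDP: SDD, upstroke, repolarisation
  add_cycle <- function(t0, v_mdp, v_mdp_next) {
    add_seg(t0, t0 + d1, "lin", v_mdp, preset$takeoff)
    add_seg(t0 + d1, t0 + d1 + d2, "lin", preset$takeoff, preset$ap_peak)
    add_seg(t0 + d1 + d2, t0 + period, "repol", preset$ap_peak, v_mdp_next)
    ap_times <<- c(ap_times, t0 + d1)       # upstroke onset = takeoff time
    invisible(t0 + period)
  }

  mdp_at <- function(elapsed_in_bout) {
    max(preset$mdp_end, preset$mdp_onset + drift_rate * elapsed_in_bout)
  }

  # a firing bout beginning with an AP fired directly off the silent ramp
  # (or recording start); returns the end time (= repol end of last AP)
  # and the final MDP the bout settled at
  add_bout <- function(t0, bout_len, v_from, lead_ap = TRUE) {
    t <- t0
    if (lead_ap) {
      add_seg(t, t + d2, "lin", v_from, preset$ap_peak)
      ap_times <<- c(ap_times, t)
      add_seg(t + d2, t + d2 + d3, "repol", preset$ap_peak, preset$mdp_onset)
      t <- t + d2 + d3
    }
    n_cyc <- max(1L, round((bout_len - (t - t0)) / period))
    v1 <- preset$mdp_onset
    for (j in seq_len(n_cyc)) {
      v0 <- mdp_at(t - t0)
      v1 <- mdp_at(t + period - t0)
      add_cycle(t, v0, v1)
      t <- t + period
    }
    list(t = t, v_end = v1)
  }

  add_ramp <- function(t0, len, v_from) {
    add_seg(t0, t0 + len, "ramp", v_from, v_from + preset$delta_vm)
    ep_start <<- c(ep_start, t0); ep_end <<- c(ep_end, t0 + len)
    ep_v0 <<- c(ep_v0, v_from); ep_v1 <<- c(ep_v1, v_from + preset$delta_vm)
    t0 + len
  }

  if (f == 0) {
    t <- 0
    while (t < duration) t <- add_cycle(t, preset$mdp_onset, preset$mdp_onset)
  } else {
    # stationary start: pick state by its time share, length-bias the
    # first interval and enter it at a uniform elapsed phase
    silent_first <- stats::runif(1) < f
    if (silent_first) {
      L <- length_biased(rand_silent, preset$mean_episode_s,
                         preset$episode_sd_s)
    } else {
      L <- length_biased(rand_bout, bout_mu, bout_sd)
    }
    elapsed <- stats::runif(1) * L
    t <- -elapsed
    state_silent <- silent_first
    first <- TRUE
    v_bout_end <- preset$mdp_end
    while (t < duration) {
      if (state_silent) {
        len <- if (first) L else rand_silent()
        t <- add_ramp(t, len, v_bout_end)
        state_silent <- FALSE
      } else {
        len <- if (first) L else rand_bout()
        res <- add_bout(t, len, v_bout_end + preset$delta_vm,
                        lead_ap = !first)
        t <- res$t
        v_bout_end <- res$v_end
        state_silent <- TRUE
      }
      first <- FALSE
    }
  }

  # --- sample the schedule on the uniform grid ----------------------------
  n <- floor(duration * sampling_rate) + 1L
  tt <- (seq_len(n) - 1L) / sampling_rate
  v <- numeric(n)
  for (s in segs) {
    if (s$t1 <= 0 || s$t0 > duration) next
    i0 <- max(1L, ceiling(s$t0 * sampling_rate - 1e-9) + 1L)
    i1 <- min(n, floor(s$t1 * sampling_rate + 1e-9) + 1L)
    if (i1 < i0) next
    u <- (tt[i0:i1] - s$t0) / (s$t1 - s$t0)
    v[i0:i1] <- switch(s$type,
      lin   = s$a + (s$b - s$a) * u,
      repol = s$b + (s$a - s$b) * (1 + cos(pi * u)) / 2,
      ramp  = s$a + (s$b - s$a) * (1 - cos(pi * u)) / 2)
  }
  if (preset$noise_sd > 0) v <- v + stats::rnorm(n, 0, preset$noise_sd)
  v <- v + preset$ljp_offset

  keep_ap <- ap_times >= 0 & ap_times <= duration
  edge <- ep_start < 0 | ep_end > duration
  episodes <- data.frame(
    start = pmax(ep_start, 0), end = pmin(ep_end, duration),
    duration = ep_end - ep_start,
    v_onset = ep_v0 + preset$ljp_offset,
    v_term = ep_v1 + preset$ljp_offset, edge = edge)
  episodes <- episodes[episodes$end > episodes$start, , drop = FALSE]

  out <- uniform_trace(v, sampling_rate, units = "mV")
  out$events <- list(ap_times = ap_times[keep_ap], episodes = episodes,
                     preset = preset)
  out
}

# ---- RNG / truncated-normal helpers --------------------------------------

# seed the session RNG from a single integer, restoring it afterwards is
# the caller's business; generators are documented as consuming the stream
withr_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
}

# one draw from normal(mean, sd) truncated below at lo
rtruncnorm1 <- function(mean, sd, lo) {
  if (sd <= 0) return(max(mean, lo))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo) return(x)
  }
}

# mean of the lower-truncated normal
truncnorm_mean <- function(mean, sd, lo) {
  if (sd <= 0) return(max(mean, lo))
  a <- (lo - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# underlying mu whose lower-truncated mean equals target
solve_truncnorm_mu <- function(target, sd, lo) {
  if (sd <= 0 || target <= lo) return(target)
  g <- function(mu) truncnorm_mean(mu, sd, lo) - target
  stats::uniroot(g, lower = lo - 6 * sd, upper = target + sd,
                 tol = 1e-9)$root
}

# length-biased draw via rejection against an upper cap
length_biased <- function(rdraw, mean, sd) {
  cap <- mean + 8 * sd
  repeat {
    x <- rdraw()
    if (stats::runif(1) < min(x, cap) / cap) return(x)
  }
}
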