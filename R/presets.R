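#' Pacemaker-cell preset
#'
#' Bundle of waveform and episode statistics that drives
#' [gen_pacemaker_trace()]. The waveform is a stylized sinoatrial action
#' potential: linear slow diastolic depolarisation (SDD) from the maximum
#' diastolic potential (MDP) to a takeoff potential, a fast linear upstroke,
#' and a half-cosine repolarisation back to the next MDP. Across a firing
#' bout the MDP drifts from `mdp_onset` towards `mdp_end`; nonfiring episodes
#' depolarise smoothly by `delta_vm`.
#'
#' When `ap_peak` is `NULL` it is calibrated in closed form so that the time
#' average of one bout-onset firing cycle equals `mdp_onset + 16` mV (the
#' firing/nonfiring cycle model underlying the generator relates a −67 mV
#' bout-onset MDP to a −51 mV cycle-average potential).
#'
#' @param name preset label.
#' @param firing_rate firing rate within bouts, AP/s.
#' @param mdp_onset MDP at the start of a firing bout, mV.
#' @param mdp_end MDP at the end of a firing bout, mV.
#' @param ap_peak action-potential peak, mV, or `NULL` to calibrate.
#' @param sdd_slope slope of the slow diastolic depolarisation, mV/s.
#' @param takeoff takeoff potential ending the SDD, mV.
#' @param upstroke_s upstroke duration, s.
#' @param delta_vm depolarisation across a nonfiring episode, mV.
#' @param mean_episode_s,episode_sd_s mean and SD of nonfiring episode
#'   durations, s (truncated normal floored at 3.5 s).
#' @param frac_nonfiring long-run fraction of time spent nonfiring, in [0, 1).
#' @param episodic_cell_prob probability that a cell of this condition is
#'   episodic rather than permanently firing (population metadata; the
#'   single-trace generator applies `frac_nonfiring` directly).
#' @param noise_sd white-noise SD added to the emitted trace, mV.
#' @param ljp_offset liquid-junction-potential offset added uniformly to the
#'   emitted trace, mV.
#' @return An object of class `pacemaker_preset`.
#' @seealso [san_presets()] for the shipped condition presets.
#' @export
pacemaker_preset <- function(name = "custom",
                             firing_rate = 5,
                             mdp_onset = -67,
                             mdp_end = -75,
                             ap_peak = NULL,
                             sdd_slope = 130,
                             takeoff = -45,
                             upstroke_s = 0.004,
                             delta_vm = 8,
                             mean_episode_s = 20,
                             episode_sd_s = 6,
                             frac_nonfiring = 0,
                             episodic_cell_prob = 0,
                             noise_sd = 0.3,
                             ljp_offset = 0) {
  stopifnot(firing_rate > 0, sdd_slope > 0, upstroke_s > 0,
            noise_sd >= 0, episode_sd_s >= 0)
  if (frac_nonfiring < 0 || frac_nonfiring >= 1) {
    stop("'frac_nonfiring' must lie in [0, 1)")
  }
  if (frac_nonfiring > 0 && mean_episode_s < 3.5) {
    stop("'mean_episode_s' must be >= 3.5 s when frac_nonfiring > 0")
  }
  if (!(mdp_end < mdp_onset)) stop("need mdp_end < mdp_onset")
  if (!(takeoff > mdp_onset)) stop("takeoff must be above mdp_onset")
  if (is.null(ap_peak)) {
    ap_peak <- calibrate_ap_peak(firing_rate, mdp_onset, sdd_slope,
                                 takeoff, upstroke_s)
  }
  if (!(mdp_onset < ap_peak)) stop("need mdp_onset < ap_peak")
  structure(
    list(name = name, firing_rate = firing_rate, mdp_onset = mdp_onset,
         mdp_end = mdp_end, ap_peak = ap_peak, sdd_slope = sdd_slope,
         takeoff = takeoff, upstroke_s = upstroke_s, delta_vm = delta_vm,
         mean_episode_s = mean_episode_s, episode_sd_s = episode_sd_s,
         frac_nonfiring = frac_nonfiring,
         episodic_cell_prob = episodic_cell_prob,
         noise_sd = noise_sd, ljp_offset = ljp_offset),
    class = "pacemaker_preset")
}

#' @export
print.pacemaker_preset <- function(x, ...) {
  cat(sprintf("pacemaker_preset '%s':\n", x$name))
  cat(sprintf("  firing %g AP/s, MDP %g -> %g mV, peak %.2f mV, SDD %g mV/s\n",
              x$firing_rate, x$mdp_onset, x$mdp_end, x$ap_peak, x$sdd_slope))
  cat(sprintf(
    "  nonfiring: frac %.3f, episodes %.1f +/- %.1f s, dVm %.2f mV\n",
    x$frac_nonfiring, x$mean_episode_s, x$episode_sd_s, x$delta_vm))
  invisible(x)
}

# Closed-form calibration of the AP peak: the time average of one
# MDP-to-MDP cycle (linear SDD + linear upstroke + half-cosine
# repolarisation, stationary MDP) is set to mdp_onset + 16 mV.
calibrate_ap_peak <- function(firing_rate, mdp_onset, sdd_slope,
                              takeoff, upstroke_s,
                              target_offset = 16) {
  period <- 1 / firing_rate
  d1 <- (takeoff - mdp_onset) / sdd_slope
  d3 <- period - d1 - upstroke_s
  if (d3 <= 0) {
    stop("waveform inconsistent: SDD + upstroke exceed the firing period")
  }
  target <- mdp_onset + target_offset
  # target * T = d1*(mdp+takeoff)/2 + d2*(takeoff+peak)/2 + d3*(peak+mdp)/2
  rhs <- target * period -
    d1 * (mdp_onset + takeoff) / 2 -
    upstroke_s * takeoff / 2 -
    d3 * mdp_onset / 2
  peak <- rhs / ((upstroke_s + d3) / 2)
  if (peak <= takeoff) stop("calibrated peak fell below takeoff potential")
  peak
}

#' Shipped pacemaker condition presets
#'
#' Returns the named list of [pacemaker_preset()]s for the study conditions:
#' wild type (`"WT"`) and CDR-deficient knockin (`"HCN4FEA"`) cells under
#' basal conditions, both genotypes under isoproterenol, and wild type after
#' TAT-TRIP8b block of cAMP-dependent regulation. Episode statistics carry
#' the measured condition values (mean nonfiring episode duration, fraction
#' of time nonfiring, per-episode depolarisation, episodic-cell incidence).
#'
#' @param name optional preset name; when given, that single preset is
#'   returned.
#' @return A named list of `pacemaker_preset` objects, or one preset.
#' @export
san_presets <- function(name = NULL) {
  p <- list(
    WT = pacemaker_preset(
      name = "WT", frac_nonfiring = 0.064, episodic_cell_prob = 0.42,
      mean_episode_s = 16.2, episode_sd_s = 5, delta_vm = 8.16),
    HCN4FEA = pacemaker_preset(
      name = "HCN4FEA", frac_nonfiring = 0.377, episodic_cell_prob = 0.90,
      mean_episode_s = 28.9, episode_sd_s = 10, delta_vm = 7.17),
    `WT+iso` = pacemaker_preset(
      name = "WT+iso", firing_rate = 6.5, sdd_slope = 180,
      frac_nonfiring = 0, episodic_cell_prob = 0,
      mean_episode_s = 16.2, episode_sd_s = 5, delta_vm = 8.16),
    `HCN4FEA+iso` = pacemaker_preset(
      name = "HCN4FEA+iso", firing_rate = 6.5, sdd_slope = 180,
      frac_nonfiring = 0.15, episodic_cell_prob = 0.571,
      mean_episode_s = 10, episode_sd_s = 3, delta_vm = 7.17),
    `WT+TRIP8b` = pacemaker_preset(
      name = "WT+TRIP8b", frac_nonfiring = 0.45, episodic_cell_prob = 1,
      mean_episode_s = 30, episode_sd_s = 10, delta_vm = 8.16)
  )
  if (is.null(name)) return(p)
  if (!name %in% names(p)) {
    stop("unknown pacemaker preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  }
  p[[name]]
}

#' HCN channel preset
#'
#' Parameters of a steady-state activation curve and activation/deactivation
#' kinetics used by [gen_activation_dataset()] and [gen_current_trace()].
#'
#' @param name preset label.
#' @param v05 half-maximal activation voltage, mV.
#' @param k Boltzmann slope factor, mV (> 0).
#' @param imax,imin upper and lower plateau of the (tail) current; for
#'   normalized activation datasets these default to 1 and 0.
#' @param tau1,tau2 slow and fast exponential time constants, s
#'   (`tau1 > tau2 > 0`).
#' @param a1_frac fraction of the total amplitude carried by the slow
#'   component, in [0, 1].
#' @param delay initial delay before the exponential time course, s.
#' @param holding_potential holding potential the protocol starts from, mV.
#' @return An object of class `channel_preset`.
#' @seealso [hcn_presets()]
#' @export
channel_preset <- function(name = "custom", v05 = -100, k = 10,
                           imax = 1, imin = 0,
                           tau1 = 1.2, tau2 = 0.25, a1_frac = 0.6,
                           delay = 0.05, holding_potential = -40) {
  if (k <= 0) stop("slope factor 'k' must be > 0")
  if (a1_frac < 0 || a1_frac > 1) stop("'a1_frac' must lie in [0, 1]")
  if (!(tau1 > tau2 && tau2 > 0)) stop("need tau1 > tau2 > 0")
  if (!(imin < imax)) stop("need imin < imax")
  structure(
    list(name = name, v05 = v05, k = k, imax = imax, imin = imin,
         tau1 = tau1, tau2 = tau2, a1_frac = a1_frac, delay = delay,
         holding_potential = holding_potential),
    class = "channel_preset")
}

#' @export
print.channel_preset <- function(x, ...) {
  cat(sprintf("channel_preset '%s': V0.5 %g mV, k %g mV, HP %g mV\n",
              x$name, x$v05, x$k, x$holding_potential))
  cat(sprintf("  I in [%g, %g]; tau1 %g s, tau2 %g s, a1 %g, delay %g s\n",
              x$imin, x$imax, x$tau1, x$tau2, x$a1_frac, x$delay))
  invisible(x)
}

#' Shipped HCN activation presets per holding potential
#'
#' Wild-type HCN4 steady-state activation presets measured without and with
#' saturating cAMP, from holding potentials of −55, −65 and −75 mV
#' (corresponding to membrane potentials during the firing and nonfiring
#' modes). The half-activation voltages are the measured condition means;
#' the slope factor defaults to 10 mV for every condition.
#'
#' @param name optional preset name; when given, that single preset is
#'   returned.
#' @return A named list of [channel_preset()] objects, or one preset.
#' @export
hcn_presets <- function(name = NULL) {
  mk <- function(nm, v05, hp) {
    channel_preset(name = nm, v05 = v05, holding_potential = hp)
  }
  p <- list(
    wt_nocamp_hp55 = mk("wt_nocamp_hp55", -100.1, -55),
    wt_nocamp_hp65 = mk("wt_nocamp_hp65", -90.7, -65),
    wt_nocamp_hp75 = mk("wt_nocamp_hp75", -77.6, -75),
    wt_camp_hp55   = mk("wt_camp_hp55", -82.1, -55),
    wt_camp_hp65   = mk("wt_camp_hp65", -62.0, -65),
    wt_camp_hp75   = mk("wt_camp_hp75", -51.3, -75)
  )
  if (is.null(name)) return(p)
  if (!name %in% names(p)) {
    stop("unknown channel preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  }
  p[[name]]
}
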