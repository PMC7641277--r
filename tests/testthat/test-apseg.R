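make_episodic <- function(seed = 1, duration = 120,
                          preset = san_presets("HCN4FEA")) {
  gen_pacemaker_trace(preset, duration, seed = seed)
}

test_that("detect_aps finds exactly the programmed APs", {
  p <- san_presets("WT")
  tr <- gen_pacemaker_trace(p, 60, seed = 2)
  aps <- detect_aps(tr)
  truth <- tr$events$ap_times
  expect_equal(length(aps), length(truth))
  expect_lt(max(abs(aps - truth)), 0.006)   # within the upstroke
})

test_that("flat traces give no events; a lone AP gives one", {
  flat <- uniform_trace(rep(-70, 5000), 1000)
  expect_identical(detect_aps(flat), numeric(0))
  p <- pacemaker_preset(frac_nonfiring = 0, noise_sd = 0)
  tr <- gen_pacemaker_trace(p, 1 / p$firing_rate, seed = 1)
  expect_equal(length(detect_aps(tr)), 1L)
})

test_that("ap_features reports rate, MDP and SDD slope of the generator", {
  p <- pacemaker_preset(frac_nonfiring = 0, noise_sd = 0)
  tr <- gen_pacemaker_trace(p, 30, seed = 1)
  fe <- ap_features(tr)
  expect_equal(fe$firing_rate_min, 300, tolerance = 0.01)
  expect_equal(fe$firing_rate, 5, tolerance = 1e-3)
  # bout-onset MDP preset of -67 mV shows up as the first-cycle MDP
  expect_equal(fe$mdp_per_cycle[1], -67, tolerance = 0.5)
  expect_lt(abs(fe$sdd_slope - p$sdd_slope) / p$sdd_slope, 0.02)
  expect_error(ap_features(uniform_trace(rep(-70, 40000), 1000)),
               "insufficient|no firing|APs")
})

test_that("continuous firing segments to a permanent cell with 0% nonfiring", {
  p <- pacemaker_preset(frac_nonfiring = 0)
  tr <- gen_pacemaker_trace(p, 60, seed = 1)
  seg <- segment_modes(tr)
  expect_equal(seg$pct_nonfiring, 0)
  expect_equal(seg$cell_class, "permanent")
  expect_true(all(seg$episodes$mode == "firing"))
})

test_that("segmentation partition identity holds exactly", {
  for (s in 1:3) {
    tr <- make_episodic(seed = s, duration = 200)
    seg <- segment_modes(tr)
    expect_equal(sum(seg$episodes$end - seg$episodes$start),
                 trace_duration(tr), tolerance = 1e-9)
    # episodes tile without overlap
    expect_true(all(abs(seg$episodes$start[-1] -
                          seg$episodes$end[-nrow(seg$episodes)]) < 1e-9))
  }
})

test_that("interior episodes recover programmed duration and delta Vm;
           a >=10 s episode makes the cell episodic", {
  p <- san_presets("HCN4FEA")
  durs <- dvms <- truth <- numeric(0)
  classes <- character(0)
  for (s in 1:5) {
    tr <- make_episodic(seed = s, duration = 300, preset = p)
    seg <- segment_modes(tr)
    durs <- c(durs, seg$nonfiring_durations)
    dvms <- c(dvms, seg$delta_vm)
    truth <- c(truth, tr$events$episodes$duration[!tr$events$episodes$edge])
    classes <- c(classes, seg$cell_class)
  }
  expect_equal(length(durs), length(truth))
  expect_lt(max(abs(sort(durs) - sort(truth))), 0.25)
  expect_lt(abs(mean(dvms) - p$delta_vm), 0.15)
  expect_true(any(classes == "episodic"))
  expect_true(all(durs >= 3.5))
})

test_that("a 5-s gap counts towards statistics but not episodic class", {
  # build a trace with exactly one ~5 s silent gap by hand: firing,
  # silence at MDP level, firing
  p <- pacemaker_preset(frac_nonfiring = 0, noise_sd = 0)
  a <- gen_pacemaker_trace(p, 20, seed = 1)
  b <- gen_pacemaker_trace(p, 20, seed = 1)
  gap <- uniform_trace(rep(-70, 5 * 1000), 1000)
  v <- c(a$values, gap$values, b$values)
  tr <- uniform_trace(v, 1000)
  seg <- segment_modes(tr)
  expect_equal(seg$cell_class, "permanent")
  expect_equal(sum(seg$episodes$mode == "nonfiring"), 1L)
  expect_gt(seg$pct_nonfiring, 8)   # ~5 s of 45 s
  expect_lt(seg$pct_nonfiring, 15)
})

test_that("silent gaps far from the MDP band are not nonfiring episodes", {
  p <- pacemaker_preset(frac_nonfiring = 0, noise_sd = 0)
  a <- gen_pacemaker_trace(p, 20, seed = 1)
  gap <- uniform_trace(rep(-20, 6 * 1000), 1000)  # way above MDP - gate
  v <- c(a$values, gap$values, a$values)
  seg <- segment_modes(uniform_trace(v, 1000))
  expect_equal(sum(seg$episodes$mode == "nonfiring"), 0L)
})

test_that("lowering frac_nonfiring never raises measured nonfiring time", {
  base <- san_presets("HCN4FEA")
  lower <- pacemaker_preset(name = "lower", frac_nonfiring = 0.15,
                            mean_episode_s = base$mean_episode_s,
                            episode_sd_s = base$episode_sd_s,
                            delta_vm = base$delta_vm)
  for (s in 1:3) {
    hi <- segment_modes(gen_pacemaker_trace(base, 300, seed = s))
    lo <- segment_modes(gen_pacemaker_trace(lower, 300, seed = s))
    expect_lte(lo$pct_nonfiring, hi$pct_nonfiring)
  }
})

test_that("segmentation demands firing and a 30-s trace", {
  expect_error(segment_modes(uniform_trace(rep(-70, 40 * 1000), 1000)),
               "no firing")
  p <- pacemaker_preset(frac_nonfiring = 0)
  tr <- gen_pacemaker_trace(p, 10, seed = 1)
  expect_error(segment_modes(tr), "30 s")
})

test_that("dose_response normalizes to the basal rate", {
  d <- data.frame(concentration = c(10, 100, 1000),
                  firing_rate = c(300, 150, 30))
  out <- dose_response(d, basal = 300)
  expect_equal(out$pct_reduction, c(0, 50, 90))
  expect_error(dose_response(d, basal = 0), "> 0")
  # programmed reductions recover exactly through a generated rate table
  basal <- 320
  red <- c(5, 35, 80)
  tab <- data.frame(concentration = c(1, 10, 100),
                    firing_rate = basal * (1 - red / 100))
  expect_equal(dose_response(tab, basal)$pct_reduction, red)
})
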