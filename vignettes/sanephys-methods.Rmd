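---
title: "Methods: models, generators and numerical choices in sanephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in sanephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanephys)
```

## Scope and scientific background

The sinoatrial node (SAN) initiates every heartbeat. Its pacemaker cells
depolarise spontaneously between action potentials (the slow diastolic
depolarisation, SDD), driven in part by the hyperpolarization-activated
"funny" current I~f~ carried by HCN4 channels. HCN4 gating is modulated by
cAMP: β-adrenergic input raises cAMP and shifts the channel's activation
curve to more depolarised potentials, vagal input lowers it. A central
observation this package is built around is that single SAN cells are not
obligate oscillators: they can drop into a *nonfiring mode* — a slow
hyperpolarisation terminating firing, a silent period of seconds to a
minute at near-diastolic potentials, then a slow depolarisation until
firing resumes. The balance between firing and nonfiring cells, set by
cAMP-dependent regulation of HCN4, shapes heart rate, heart-rate
variability (HRV), baroreflex responses and sinoatrial conduction.

`sanephys` implements the measurement pipeline around this biology:

* voltage-clamp curve fitting (`fit_boltzmann`, `fit_exponential`,
  `current_density`, `ica_decompose`);
* action-potential detection and firing/nonfiring segmentation
  (`detect_aps`, `ap_features`, `segment_modes`, `dose_response`);
* murine HRV in the time and frequency domain (`summarize_rate`,
  `time_domain`, `spectral_hrv`, `poincare`, `detect_pauses`);
* baroreflex sequence analysis (`scan_sequences`);
* programmed-stimulation conduction measures (`compute_snrt`,
  `compute_sact`, `av_conduction_curves`, `find_erp`);
* optical activation mapping (`activation_map`, `optical_sact`,
  `pacemaker_shift`, `dff`, `subthreshold_density`).

Because the original animal recordings are not distributable, every
analysis is paired with a seeded synthetic generator that emits data with
the statistical structure the analysis assumes. The generators are
first-class, tested code: each analysis is verified by round-trip recovery
of the generator's programmed parameters, and independently against
brute-force oracles in the test suite.

## The Boltzmann activation model

Steady-state activation of HCN currents is summarised by the half-maximal
activation voltage $V_{0.5}$ and slope factor $k$ of

$$\frac{I - I_{min}}{I_{max} - I_{min}} =
  \frac{1}{1 + \exp\!\big((V_m - V_{0.5})/k\big)},\qquad k > 0,$$

so activation grows towards $I_{max}$ with hyperpolarisation and equals
$(I_{min}+I_{max})/2$ at $V_m = V_{0.5}$. Protocol conventions sometimes
print this relation without the logistic denominator, which is unbounded
and does not place half-activation at $V_{0.5}$; `fit_boltzmann` uses the
standard logistic form, which satisfies the definition of $V_{0.5}$ as the
half-maximal point. Fitting is Levenberg–Marquardt least squares
(`minpack.lm`) with $k$ bounded positive. The starting point places
$V_{0.5}$ at the interpolated half-range crossing with $k = 10$ mV;
because the optimizer's path can be sensitive to the exact start, a short
ladder of alternative starts is tried and the first converged fit kept.
Flat or non-sigmoidal inputs fail with an explicit "no sigmoid structure"
error rather than returning nonsense.

`hcn_presets()` ships the wild-type condition presets measured from
holding potentials of −55, −65 and −75 mV without and with saturating
cAMP ($V_{0.5}$ from −100.1 to −51.3 mV). Slope factors per condition are
not individually published in the main text; all presets default to
$k = 10$ mV, a typical HCN4 value.

Kinetics are fitted with
$I(t) = I_{ss} + A_1 e^{-t/\tau_1} (+\, A_2 e^{-t/\tau_2})$ after an
initial delay. When the delay is not supplied it is estimated as the time
at which 10% of the total amplitude change has occurred — a conservative
reading of "after an initial delay" that guarantees the fitted stretch is
past any sigmoidal onset. Samples before the delay are excluded; time is
referenced to the start of the analysed stretch so amplitudes are
comparable across traces. An order-2 fit applied to single-exponential
data collapses to $\tau_2 \approx \tau_1$; this is flagged `degenerate` in
the result rather than raised as an error, since it is a legitimate model
comparison outcome.

## The stylized pacemaker waveform and its calibration

The descriptive model of the firing/nonfiring cycle fixes only a few
voltages: firing bouts start at a maximum diastolic potential (MDP) of
−67 mV and drift to −75 mV; the cycle-average potential at bout onset is
−51 mV; across a nonfiring episode the membrane depolarises by
$\Delta V_m$ (7.17 mV for the cAMP-insensitive knockin, 8.16 mV for wild
type). No full waveform is specified, so `gen_pacemaker_trace` uses a
piecewise stylized action potential:

* linear SDD from the MDP to a takeoff potential (default −45 mV,
  130 mV/s — realistic murine SAN values chosen once);
* a 4-ms linear upstroke to the AP peak;
* a half-cosine repolarisation back to the next MDP, filling the rest of
  the firing period (default 300 AP/min).

The AP peak is not treated as a free aesthetic choice: it is solved in
closed form so that the time average of one bout-onset MDP-to-MDP cycle
equals `mdp_onset + 16` mV, reproducing the −67 → −51 mV relation. With
the default geometry this calibration lands the peak near +17 mV, inside
the physiological range; the peak is thus a calibration artifact, not a
measured value.

Nonfiring episodes are generated as a half-cosine depolarising ramp of
exactly `delta_vm` from the bout-end MDP, ending at the takeoff of the
next bout's first action potential. The cosine shape has near-zero slope
at both ends, so the onset/termination potentials measured 100 ms inside
the episode (the segmentation convention, chosen to avoid AP transients)
differ from the programmed `delta_vm` by well under 0.1%.

### Episode scheduling

Episode durations are drawn from a normal distribution truncated below at
3.5 s — the shortest episode admitted to statistics. The preset means are
the measured condition values (28.9 s knockin, 16.2 s wild type); the
published dispersions are standard errors without episode counts, so the
generator's standard deviations (10 s and 5 s, coefficient of variation
≈ 0.33) are package choices fixed once. Firing-bout durations are drawn
from a truncated normal whose mean is solved (by `uniroot` on the
truncated-normal mean) so that the long-run silent-time fraction equals
the preset `frac_nonfiring` (0.377 knockin, 0.064 wild type) after
truncation effects.

The alternating firing/silent renewal process is started in its
stationary regime: the initial state is chosen by its time share, the
first interval is drawn length-biased (rejection sampling against an
upper cap at mean + 8 SD), and entry is at a uniform phase. This makes
the expected silent fraction equal to `frac_nonfiring` over *any*
recording window, not only asymptotically — important because the
ensembles analysed are 600-s windows, short relative to wild-type firing
bouts (~4 min).

`episodic_cell_prob` (fraction of cells of a condition that are episodic
at all) is carried as preset metadata for population-level simulation; the
single-trace generator applies `frac_nonfiring` directly, because the
published nonfiring-time percentages are population means over all cells.

### Segmentation conventions

`segment_modes` implements the published categorisation rules: silent
gaps of at least 3.5 s whose mean potential lies within ±10 mV of the
trace's average firing-cycle MDP are nonfiring episodes; a cell is
*episodic* if any episode reaches 10 s, *permanent* otherwise. Episode
onsets are located at the end of the last AP's repolarisation (first
non-negative smoothed slope after the post-AP downstroke) and
terminations at the next AP's takeoff. Episodes truncated by the
recording window are counted in the percentage of nonfiring time but
excluded from duration and $\Delta V_m$ statistics, one consistent
reading of how a 10-s categorisation threshold and a 3.5-s statistics
floor coexist. This exclusion carries a small inspection-paradox bias
(long episodes are more likely to hit a window edge), on the order of a
few percent for 600-s windows; it is a property of the estimator design,
shared by any finite-window analysis of these rules.

AP detection places events at the maximum-upstroke-velocity sample behind
an amplitude gate (the upstroke must cross the midpoint between the
trace's extreme potentials) with a 30-ms refractory guard. The SDD slope
is a linear fit from the MDP to the takeoff point where the smoothed
dV/dt first exceeds three times the median diastolic dV/dt — SDD slopes
are conventionally reported without a defined window, and this takeoff
criterion recovers the generator's programmed slope to well under 2%.

## HRV pipeline

The murine spectral pipeline is implemented literally: a 103-s RR
tachogram (RR assigned to the time of its terminating beat) is resampled
by cubic spline at 50-ms intervals (20 Hz), giving 2060 points of which
the first 2048 form the analysis stretch — exactly covering three
half-overlapping 1024-point Hamming windows (asserted at run time). The
stretch is linearly detrended once (the method for "after detrending" is
not specified; a linear fit is the least committal choice), each window's
periodogram is compensated by the window power, and the one-sided
averaged spectrum is integrated by the trapezoidal rule over VLF
(0–0.4 Hz), LF (0.4–1.5 Hz) and HF (1.5–4.0 Hz). Band edges that fall
between grid points are linearly interpolated into the integration, so
VLF + LF + HF equals the 0–4 Hz total power to machine precision by
construction, and the grid resolution is 20/1024 ≈ 0.0195 Hz.
"Half overlapping" is read as exactly 50% overlap. Time-domain measures
(SDNN, RMSSD) are computed per segment and averaged across segments;
artifact filtering (RR outside mean ± 4 SD) exists but is off by default
— the caller supplies cleaned sinus-rhythm series.

## Baroreflex sequences

`scan_sequences` scans every beat triple for monotone SBP ramps of at
least 0.5 mmHg per step with the RR interval responding one beat later by
at least 2 ms per step in the same direction; the slope of the RR-on-SBP
regression is kept when $|r| > 0.85$. Overlapping triples count
separately (a 4-beat ramp yields two sequences): the sequence length is
fixed at three beats and no merging rule is published. Thresholds compare
with `>=`, reading "threshold" as the minimum qualifying change. With
three points the correlation gate rarely rejects unless the middle beat
inverts; it is implemented literally anyway, and the test suite re-audits
every reported sequence against its own thresholds.

## Programmed stimulation

`compute_sact` follows the classic premature-atrial-stimulation logic:
return cycles satisfying the fully compensatory identity
$|A_1A_2 + A_2A_3 - 2\,A_1A_1| \le \varepsilon$ lie on the diagonal;
scanning couplings downward, the first row deviating beyond
$\varepsilon$ with $A_2A_3 > A_1A_1$ marks the reset zone, and SACT is
$(A_2A_3 - A_1A_1)/2$ there. $\varepsilon$ defaults to 5 ms (≈2.5% of a
200-ms murine cycle length) since the original determination is
graphical. Two design details matter under measurement jitter: a
deviating row must be confirmed by the next row (or be the shortest
coupling tested), so a single jittered compensatory row cannot
masquerade as the reset onset; and because the reset plateau is flat,
SACT is insensitive to exactly which plateau row is selected — the
plateau mean is available as `method = "plateau"`. Whether the original
analysis used the first deviating point or a plateau mean is ambiguous;
first-deviation is the default. The A3A4/A1A1 comparison is exposed as
an automaticity ratio without a threshold, since none is published.

## Optical mapping

Per-pixel activation time is the midpoint of the frame step with the
maximum temporal derivative of the normalized, polarity-corrected signal
(voltage-dye emission falls on depolarisation, hence `invert = TRUE` by
default). Maximum dF/dt is the standard criterion for optical upstrokes;
a 50%-crossing criterion would behave identically on the symmetric
synthetic upstrokes. Pixels whose relative amplitude falls below 20% of
the median are masked out. Times are referenced to the earliest pixel
(the leading pacemaker site); the absolute reference is retained in
`t_ref_ms`, and per-pixel absolute error on noiseless planar waves is at
most half a frame. When an upstroke centre falls exactly between two
frames the choice between the adjacent half-frames is a floating-point
tie; tests avoid asserting through such degenerate geometries.

## What the generators do and do not emulate

The generators reproduce the *statistical structure the analyses assume*:
episode alternation and its stationary occupancy, sigmoid activation with
additive noise, exponential kinetics, sinusoidally modulated tachograms
with injectable pauses, lag-1 coupled SBP–RR ramps on a flat baseline,
compensatory/reset return-cycle geometry, and constant-velocity planar
waves. They do not emulate biophysics: there is no conductance-based SAN
model, no beat-to-beat coupling between waveform shape and cycle length,
no respiratory or thermoregulatory nonstationarity, no ECG morphology,
and no arrhythmia (junctional escape, AV dissociation). Passing tests
therefore demonstrate that the measurement pipeline is correct and
unbiased under the stated assumptions — not that those assumptions
exhaust real recordings. In particular, real baroreflex data have
correlated SBP/RR fluctuations everywhere, not only inside programmed
sequences, so absolute sequence counts from the generator say nothing
about in-vivo counts; only the recovery of programmed slopes and counts
is meaningful.

## Problem sizes and reproducibility

Every generator takes a single integer seed and is bit-reproducible given
(preset, seed). The shipped test suite and the acceptance script analyse
ensembles of 30–50 traces of 600 s at 1 kHz per condition — enough for
the ensemble standard errors on episode duration, $\Delta V_m$ and
nonfiring percentage to sit well inside the published dispersions, while
keeping a full run in tens of seconds on one core. Spectral fixtures use
~1300 beats (a little over the 103-s analysis segment at 100-ms RR);
mapping fixtures use 8–16 pixel grids at 2 kHz, matching the optical
sampling rate.

## Known limitations

* The stylized AP has no APD50/90 structure; duration analytics are out
  of scope.
* The liquid-junction-potential correction linking measured to model
  potentials is not published; presets carry an `ljp_offset` applied
  uniformly, default 0.
* `segment_modes` requires ≥ 30 s of trace and at least one detected AP;
  cells silent for an entire recording cannot be classified (matching the
  experimental definition, which is anchored to an average firing MDP).
* The HRV spectral estimator is tied to the published 20-Hz/1024-point
  configuration; it is not a general-purpose Welch implementation.
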