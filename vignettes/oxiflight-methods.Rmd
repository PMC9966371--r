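---
title: "Methods: phase analysis of hypoxia-training oximetry records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase analysis of hypoxia-training oximetry records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiflight)
```

## The measurement setting

During hypoxia-awareness training in a hypobaric chamber, a crew member at a
simulated altitude near 25,000 ft removes the supplemental-oxygen mask.
Finger pulse oximetry records SpO2 and heart rate, typically at 1 Hz;
saturation falls from a baseline near 97–99% toward a nadir in the
neighbourhood of 60%, and recovers after the mask is reconnected. The mask
connection state is recorded as a binary channel alongside the vitals.
`oxiflight` analyses such records offline; real-time acquisition and the
chamber hardware are out of scope.

## The phase decomposition

All phase mathematics is relative to the record start; absolute wall-clock
time lives only in flight metadata. Mask events are the maximal runs of
`mask == 0`: DM is the first disconnected sample of a run, RM the first
reconnected sample after it, censored when the record ends disconnected.
When a record contains several disconnection intervals, phase parameters are
computed from the first one — the standard protocol has a single
disconnection/reconnection cycle — while all intervals remain available from
`detectMaskIntervals()`.

Six durations summarise the SpO2 curve (thresholds configurable,
defaults 97% desaturation / 90% hypoxia / 97% recovery):

* **DT** = RM − DM.
* **DeD**, **HD**: first time after DM at which SpO2 falls below the
  desaturation/hypoxia threshold, minus DM. The crossing primitive returns
  the first sample at or after the anchor that *begins a run* of at least
  `debounce` consecutive samples satisfying the condition; missing samples
  never satisfy it and break runs. The default debounce is 1 (no debounce),
  which keeps the primitive equivalent to a naive per-sample scan; users
  with noisy sensors can raise it (the shipped regression test uses
  debounce 3 under 1% Gaussian noise).
* **DeT**, **HT**: dwell time below the threshold over the *whole record*,
  including any pre-disconnection samples — the phase is defined over "the
  test", and a subject already desaturated before disconnection should
  count. Each sample below threshold contributes its local inter-sample
  interval; the final sample contributes the nominal interval (median of
  successive differences). This integration is robust to mildly irregular
  grids and reduces to `count × dt` on uniform ones.
* **RT**: first time at or after RM at which SpO2 is `≥` the recovery
  threshold, minus RM.

Comparison semantics are strict `<` for the falling phases and inclusive
`≥` for recovery, matching the definitions "below 97%/90%" and "until 97%
is reached". Whether the original procedure used `≤` at the boundary is not
documented anywhere we could find; on physical traces the choice only
matters when a sample sits exactly on the threshold, and integer-reporting
oximeters make 97 exactly-at-threshold common — strict `<` deliberately does
*not* count a reading of exactly 97 as desaturated.

Undefined vs censored: a parameter is *undefined* when its event can no
longer occur in principle (SpO2 never crossed the threshold during the
record, no disconnection present), and *censored* when observation ended
first (mask never reconnected, saturation still below 97% at the record
end). Censored parameters carry the observed partial duration where it is
meaningful (DT observed up to the record end) and are excluded from all
group statistics, with censored counts reported separately.

## Segment slopes and trace statistics

Slopes are ordinary least squares over the closed window, reported per
minute (the physiological convention for desaturation rates), with the
intercept evaluated at the window start. The coefficient of determination
is defined as 1 whenever residuals vanish — including the constant trace,
where the total sum of squares is 0 and the usual ratio is indeterminate.
The OLS estimator is computed in closed form; an independent `stats::lm`
fit serves as the cross-check in the test suite.

The automatic segmentation anchors three windows at the phase landmarks:
baseline `[start, DM]`, desaturation `[DM, argmin SpO2 within the
disconnection interval]`, and recovery `[RM, RM + RT]`. The original
procedure does not document how its automatic segmentation picks windows;
phase-anchored windows are this package's choice because they are
deterministic, physiologically interpretable, and reduce to the generator's
programmed decline on piecewise-linear traces. A manual refit over any
window uses the same estimator with `source = "manual"`.

## Validity checking

Visual inspection in the original workflow verified recording continuity
and the coincidence of the SpO2 response with the mask events. The
computable proxy flags: inter-sample gaps above `max_gap` (default 5 s on a
nominal 1 Hz grid), absent mask events, out-of-range SpO2, and a missing
desaturation response — SpO2 failing to fall by at least `response_drop`
(default 2%) below its level at disconnection within `response_window`
(default 120 s). The 2%/120 s defaults are deliberately lenient: they catch
detached sensors and swapped channels without rejecting slow responders,
and both are configuration, not constants.

## Cohort filters

Filter criteria (identity, age range, sex, mask state, per-parameter phase
ranges, flight type) combine by conjunction — the panel being emulated
"delimits" a sample, and AND-composition makes filters order-independent
and composable, which the property tests exercise. The flight-type taxonomy
(total, valid, day and night, day only, decompression, medical) is matched
case-insensitively against free-text flight metadata; the operational
definitions of the categories are site-specific, so they are treated as
opaque labels. `valid` is operationalised through `validateRecord()` rather
than a manual flag. Censored phase values fail range checks unless
`include_censored` is set, so a filter on RT cannot silently admit subjects
whose recovery was never observed.

## Group summaries

Cohort curves and heat maps need a common axis: each subject is shifted so
the chosen anchor maps to t = 0 and linearly interpolated onto a uniform
grid. The default anchor is the disconnection time, because the phenomenon
of interest is the post-disconnection response and the phase definitions are
DM-anchored; wall-clock alignment is available via `anchor =
"record_start"`. Per-timepoint statistics use pairwise-available data (no
listwise deletion), with `n` per timepoint reported so partial coverage is
auditable. SD is the sample standard deviation, taken as 0 when one subject
contributes to a timepoint (a curve band, not an inference); in the
descriptive summary table a singleton SD is instead NA, since there the
value feeds comparisons. Quartiles use the linear-interpolation rule
(R type 7) throughout — no quantile convention is documented for the
original tool, so one was fixed and documented. The aligned matrix is a
`SummarizedExperiment` (subjects × timepoints), and rendering is a thin
optional layer over the numeric matrix so tests target numbers, not pixels.

## The synthetic generator

No public corpus of chamber-training records exists, so the generator is a
first-class module. The noiseless SpO2 model is piecewise exponential:
baseline until DM + `desat_delay` (the delay standing in for lung and
circulatory oxygen stores), then decay toward `nadir_spo2` with time
constant `desat_tau`, then after RM recovery toward baseline with
`recovery_tau`. Exponential approach kinetics were chosen because they are
smooth, monotone and analytically invertible, which gives closed-form
ground-truth crossing times. Heart rate mirrors desaturation depth linearly
up to `hr_rise`. Defaults — 98% baseline, 60% nadir, 10 s delay, 80 s
desaturation and 25 s recovery time constants, 70 bpm baseline with a
25 bpm rise, 600 s records with DM = 60 s and RM = 360 s at 1 Hz — were
fixed once to represent a typical 25,000 ft exposure with a five-minute
mask-off period.

Outputs are quantized to integer percent and bpm, as pulse oximeters
report. Quantization moves the observable crossing boundary: a reading
below 97 first appears when the underlying signal crosses 96.5. Ground
truth therefore inverts the exponential at the effective boundary
(threshold − 0.5 when quantizing) and snaps the continuous crossing time
forward to the sample grid, i.e. the ground truth models the full forward
process. Noise (additive Gaussian) and Bernoulli dropouts are applied after
ground truth is computed, from a per-subject RNG stream derived from the
master seed by a fixed prime stride, so cohort size never perturbs earlier
subjects and identical seeds give bit-identical files. The generator does
not model alveolar gas exchange, altitude-to-SpO2 transfer, motion
artefacts, or the accuracy tiers of real oximeters (whose reading at 90%
may correspond to 86–94% true saturation) — synthetic passes therefore
demonstrate algorithmic correctness on idealised kinetics plus simple
noise, not robustness to every failure mode of field recordings.

## Numerical choices and problem sizes

* File serialization uses 15 significant digits where that round-trips the
  double exactly and 17 otherwise, so read(write(x)) is bit-exact.
* Dwell-time sums and crossing scans are exact integer-grid operations at
  1 Hz; property tests compare them against naive loops on ~100–200 random
  piecewise-linear traces, and parameter-recovery tests use 100 noiseless
  subjects with randomised kinetics — sizes chosen so the whole suite runs
  in well under a minute while exercising every branch (censoring,
  undefined phases, debounce, irregular grids).
* The slope r² threshold for "all-zero residuals" is a relative 1e-12 guard
  against floating-point residue on exact lines.
* Tie-breaks: the desaturation window ends at the *first* SpO2 minimum
  within the disconnection interval (`which.min`); quantile type 7; mask
  resampling uses previous-value hold, vitals linear interpolation.

## Known limitations

Phase parameters from records with multiple disconnection cycles reflect
only the first cycle. Channel alignment interpolates across internal
dropouts when resampling, which can smooth over short sensor losses (the
validity check still sees the raw gaps). The validity proxy cannot replace
expert review of pathological traces; it is designed to be conservative in
what it rejects. Flight-type semantics beyond `total`/`valid` are opaque
labels, and no between-group inference is provided — the tool produces
descriptive summaries only.
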