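# oxiflight

Phase analysis of pulse-oximetry records from simulated hypobaric-chamber
flights.

Aircrews train for hypoxia awareness in hypobaric chambers: at a simulated
altitude around 25,000 ft the trainee disconnects from the supplemental-oxygen
mask, peripheral oxygen saturation (SpO2) falls from a baseline near 98%
toward values around 60%, heart rate rises under sympathetic drive, and the
mask is reconnected once symptoms are recognised. `oxiflight` gives
physiologists and aerospace-medicine researchers a scriptable toolchain for
the resulting SpO2/heart-rate recordings: a plain-text file dialect for
flight records, automatic mask-event detection, decomposition of the
desaturation curve into six phase parameters, segment slope fitting, record
validity checks, declarative cohort filters, and group-level curves, heat
maps and descriptive statistics.

## The phase model

Let DM and RM be the times of disconnection from and reconnection to the
oxygen mask, read off the binary mask channel. With a desaturation threshold
of 97% SpO2 and a hypoxia threshold of 90% (the shipped defaults), the SpO2
curve s(t) is summarised by six durations:

| Parameter | Definition |
|---|---|
| DT  | disconnection time, RM − DM |
| DeD | desaturation delay: time after DM until s(t) first falls below 97% |
| HD  | hypoxia delay: time after DM until s(t) first falls below 90% |
| DeT | desaturation time: total time with s(t) < 97% during the test |
| HT  | hypoxia time: total time with s(t) < 90% during the test |
| RT  | recovery time: time after RM until s(t) reaches 97% again |

Delays use strictly `< threshold`; recovery uses `≥ threshold`. A parameter
whose event cannot occur (SpO2 never fell below the threshold) is
*undefined*; one whose event had not yet occurred when the record ended
(e.g. the mask is never reconnected) is *censored*, carries the observed
partial duration, and is excluded from group statistics by default.
Threshold-crossing detection supports a configurable debounce (minimum
number of consecutive qualifying samples) for noisy sensors.

Segment slopes are ordinary least squares over phase-anchored windows
(baseline, desaturation, recovery), reported in %·min⁻¹ or bpm·min⁻¹.

## Worked example

```r
library(oxiflight)

# a synthetic subject: mask off at 60 s, back on at 360 s, 1 Hz sampling
g  <- generateSubject(syntheticParams(seed = 7))
ph <- computePhaseParameters(g$subject)
as.data.frame(ph)
#>   parameter value_s  status censor_time_s
#> 1        DT     300 defined            NA
#> 2       DeD      14 defined            NA
#> 3        HD      31 defined            NA
#> 4       DeT     367 defined            NA
#> 5        HT     306 defined            NA
#> 6        RT      81 defined            NA
```

The subject was disconnected for DT = 300 s; SpO2 dropped below 97% after
14 s and below 90% after 31 s; over the whole test the subject spent 367 s
under 97% and 306 s under 90%, and needed 81 s after reconnection to return
to 97%. The generator's analytic ground truth (`g$truth`) reports the same
six values, which is the core correctness property of the pipeline.

A cohort workflow over files:

```r
dir.create("flights")
cmdSynth("flights", n_subjects = 8, seed = 1)       # writes FL001.json + CSVs
tab <- cmdAnalyze("flights/FL001.json", "analysis") # phase table + reports
res <- cmdSummarize("flights/FL001.json", "summary",
  filters = filterSpec(flight_type = "valid"),
  method = "mean_sd", anchor = "disconnection")
res$summary                                         # n/mean/SD/median/Q1/Q3 per parameter
```

`cmdSummarize` writes `group_curve_spo2.csv` / `group_curve_hr.csv`
(per-timepoint center and dispersion on the disconnection-aligned grid),
`heatmap_*.csv` (the subjects × time matrices), and
`descriptive_summary.csv`. The same workflow is available from a shell via
`inst/cli/oxiflight.R` with subcommands `synth`, `analyze`, `summarize` and
`validate`.

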