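# fearmotion

Digital phenotyping of child fear responses from a single waist-worn
inertial measurement unit (IMU). The package is written for
developmental-psychopathology and wearable-sensing researchers who run
instrumented mood-induction (fear-induction) tasks with young children
and want objective motion markers alongside — or instead of — human
behavioral coding.

## What it computes

A belt-worn IMU (tri-axial accelerometer + gyroscope) records the
child's torso motion through a staged threat task. Anchored at the
manually annotated startle instant *t<sub>s</sub>*, three half-open
phase windows are cut: **Potential Threat** [*t<sub>s</sub>*−23,
*t<sub>s</sub>*−3), **Startle** [*t<sub>s</sub>*−3, *t<sub>s</sub>*+3)
and **Response Modulation** [*t<sub>s</sub>*+3, *t<sub>s</sub>*+23)
seconds. A complementary filter fuses gyro and accelerometer into the
gravity direction *u*; motion is decomposed against the vertical and
summarized per phase by six measures:

| measure | definition | meaning |
|---|---|---|
| `ah_rms` | rms of ‖a − (a·u)u‖ | horizontal motion intensity (m/s²) |
| `av_rms` | rms of a·u − g₀ | vertical motion intensity (m/s²) |
| `wh_rms` | rms of ‖ω − (ω·u)u‖ | leaning speed (deg/s) |
| `wv_rms` | rms of ω·u | turning speed (deg/s) |
| `alpha_rom` | max−min tilt angle | leaning magnitude (deg) |
| `gamma_rom` | max−min yaw angle | turning magnitude (deg) |

Behavioral video codes (valence × channel × intensity × duration) are
scored as intensity-weighted seconds (×1/×2/×3 for low/moderate/high),
with ICC(2,1) inter-rater reliability. The statistical battery mirrors
the standard reporting for this design: conditional
winsorize/log cleaning, paired phase contrasts, motion–code
correlations, correlations with CBCL Internalizing/Externalizing T
scores, and pooled-variance t tests (with Cohen's d) between children
with and without internalizing diagnoses. A bundled simulator generates
complete synthetic cohorts — raw IMU CSVs, startle annotations, code
events, metadata — by exact forward kinematics, so the whole pipeline is
testable end to end without any data download.

## Worked example

```r
library(fearmotion)

cfg    <- sim_config(n_subjects = 63, seed = 42)
cohort <- simulate_cohort(cfg)
feats  <- compute_cohort_features(cohort$recordings, cohort$annotations)$features
scores <- score_fear_events(cohort$events)
tab    <- build_cohort_table(feats, scores, cohort$meta)
ana    <- analyze_cohort(clean_cohort(tab))

head(subset(ana$descriptives, phase == "PT"), 3)
#>   variable phase  n   min   max   mean     sd winsorized log_transformed
#> 1   ah_rms    PT 63 0.338  2.24  0.984  0.513       TRUE            TRUE
#> 4   av_rms    PT 63 0.275  1.68  0.759  0.383       TRUE            TRUE
#> 7   wh_rms    PT 63 6.603 44.31 20.294 10.012       TRUE           FALSE

subset(ana$phase_tests, variable == "ah_rms")
#>   variable comparison  n mean_diff      t        p
#> 1   ah_rms       PT-S 63    -0.407 -14.24 3.32e-21
#> 2   ah_rms       S-RM 63     0.228  14.32 2.52e-21
#> 3   ah_rms      PT-RM 63    -0.179  -6.03 9.93e-08

subset(ana$diagnosis_tests, phase == "PT" & variable == "ah_rms")
#>   variable phase n_none n_dx     t       p cohen_d significance
#> 1   ah_rms    PT     34   27 -2.90 0.00529   0.747          sig
```

Reading the output: horizontal motion intensity averages ~0.98 m/s²
during Potential Threat, rises sharply at Startle (negative PT−S t:
differences are first phase minus second) and falls back during
Response Modulation; children carrying the simulated internalizing
diagnosis move more during Potential Threat (negative t for
no-diagnosis minus diagnosis, d ≈ 0.75 on this single cohort). Tests are
run on the cleaned analysis scale (log where flagged); descriptives stay
in measurement units.

The same analysis runs file-to-file with the pipeline driver:

```r
cfg <- pipeline_config(paths = list(data_dir = "data", out_dir = "out"),
                       simulation = list(n_subjects = 63), seed = 42)
run_pipeline(cfg, "all")   # simulate -> extract -> score -> analyze -> report
```

which writes `feature_table.csv`, the per-table CSVs, a `report.json`
with a provenance header (config hash, seed, version) and a
human-readable `summary.txt`. A thin shell wrapper lives at
`inst/scripts/fearmotion-pipeline.R`.

Applying the pipeline to a published raw-data deposit is a
configuration exercise (the CSV reader is schema-driven and derived
per-phase feature tables are ingested directly via
`features_csv`/`read_feature_table()`); see the methods vignette.

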