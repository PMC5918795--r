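---
title: "Measuring child fear responses with a waist-worn IMU: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring child fear responses with a waist-worn IMU: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Fear-induction tasks for young children are usually quantified by human
coders scoring video, which is slow, needs extensive training, and cannot
be re-scored under a different theory of the task without re-watching
everything. A single belt-worn inertial measurement unit (IMU) — a
tri-axial accelerometer plus tri-axial gyroscope — captures the child's
full six degree-of-freedom torso motion continuously and can be
re-segmented and re-processed in seconds. `fearmotion` implements the
complete analysis chain for such an instrumented task: orientation
estimation, phase segmentation, six summary measures of motion,
intensity-weighted behavioral code scores as the comparison modality, and
the statistical battery relating both modalities to symptoms and
diagnosis.

The task model is a three-phase threat timeline anchored at the startle
instant \(t_s\) (identified manually, supplied as an annotation):

* **Potential Threat (PT)**: \([t_s - 23, t_s - 3)\) s — anticipation,
* **Startle (S)**: \([t_s - 3, t_s + 3)\) s — the immediate reaction,
* **Response Modulation (RM)**: \([t_s + 3, t_s + 23)\) s — regulation.

Windows are half-open on the right and contiguous; a sample on a boundary
belongs to the later window, and sub-sample startle times are floored to
the sample grid. This makes the per-window sample count exact and
rate-independent (2000/600/2000 samples at 100 Hz), which the tests
assert for arbitrary valid startle times. The offsets are configuration,
not constants: a different phase theory is a config edit plus a rerun.

## Orientation and the six summary measures

The torso orientation estimator is a complementary filter on the gravity
direction. Writing \(u_k\) for the unit "up" vector (opposite gravity)
expressed in the sensor frame at sample \(k\), each step first propagates
\(u\) through the gyroscope rotation — an exact Rodrigues rotation by
\(-\bar\omega_k \, \Delta t\), where \(\bar\omega_k\) is the trapezoidal
mean of the surrounding angular-rate samples — and then blends toward the
normalized accelerometer vector \(\hat a_k\):

\[ u_k \leftarrow \mathrm{normalize}\big( (1-\lambda)\, R(-\bar\omega_k
\Delta t)\, u_{k-1} + \lambda\, \hat a_k \big). \]

The blend weight \(\lambda\) defaults to 0.02 per sample at 100 Hz (time
constant ≈ 0.5 s): long-run accelerometer averaging corrects gyro drift
while short-term dynamics come from the gyro. Zero-norm accelerometer
samples skip the blend. Two angles derive from \(u\): the tilt
\(\alpha = \arccos(u \cdot e_{\mathrm{up}})\) against the configured
mounting axis (default +z; belt orientation is a config, not an
assumption), and the yaw \(\gamma = \int \omega \cdot u \; dt\). Without
a magnetometer the yaw zero is unobservable, so \(\gamma\) is anchored at
0 and only its range is meaningful — which is all the downstream measure
uses.

Motion decomposes against the estimated vertical with
\(g_0 = 9.80665\) m/s² exactly:
\(a_v = a \cdot u - g_0\), \(a_h = \lVert a - (a \cdot u) u \rVert\),
\(\omega_v = \omega \cdot u\), \(\omega_h = \lVert \omega - \omega_v u
\rVert\). Per phase, six summaries are computed: the rms of
\(a_h, a_v, \omega_h, \omega_v\) (motion intensity and speed, in m/s² and
deg/s) and the range (max − min) of \(\alpha\) and \(\gamma\) (magnitude
of leaning and turning, in degrees) — 18 values per subject. rms is
taken on the per-sample planar magnitudes, not per axis, because the
measures are defined as plane/axis intensities.

Numerical notes. The filter's vertical estimate is exact for any
gyro-consistent motion with zero linear acceleration, and the test suite
pins it against an independent quaternion-integration oracle (0.1° over
30 s in the gyro-dominant limit). Sustained *linear* sway does deflect
the vertical estimate toward the apparent gravity (any
accelerometer-based vertical must trade this off against gyro drift);
the deflection is bounded by the blend time constant and, importantly,
all summary measures are homogeneous of degree one in the motion
amplitude, so multiplicative between-subject differences — the
quantities all downstream statistics consume — pass through the filter
unchanged. No low-pass prefiltering is applied by default, since rms
measures silently change under filtering; a zero-phase 4th-order
Butterworth prefilter is available as an explicit option.

## Behavioral codes

Coded events (phase × valence × channel × intensity × duration) are
scored as intensity-weighted seconds — weight 1/2/3 for
low/moderate/high, times the interval duration, summed into one score
per subject × phase × valence × channel, with zeros filled for silent
groups of any subject present in the log. The weighting language in this
tradition is ambiguous between duration-weighting and counting weighted
intervals; duration-weighting is the default and a `method = "count"`
variant is provided. Inter-rater reliability uses ICC(2,1) — two-way
random effects, absolute agreement, single measure — the canonical form
for a pair of interchangeable blind coders rating the same subjects,
computed from the classical ANOVA mean squares and cross-checked in the
tests against `anova(lm(...))`.

## Cleaning rule and statistics

Each motion variable and behavioral score is screened: if sample
skewness > 1 and/or kurtosis > 3, the variable is winsorized at the
5th/95th empirical percentiles (type-7, linear interpolation); if still
tripped, IMU variables are natural-log transformed (behavioral scores
can be zero, so they stay on the winsorized scale). The kurtosis
threshold is interpreted on the *excess* scale (normal = 0), matching
what mainstream statistics packages print; a `kurtosis = "raw"` switch
is provided since the convention is genuinely ambiguous. Skewness and
kurtosis use the bias-corrected (type 2) estimators for the same reason.
Descriptive tables are reported on the winsorized scale (measurement
units); all tests run on the analysis scale — the same convention as
reporting descriptives before transformation and testing after. One
subtlety the screening rule creates on its own: applied per column it
can log-transform one phase of a variable but not another, which would
make paired phase contrasts compare different scales. The cohort-level
cleaner therefore harmonizes the decision within each variable family —
if any phase of a motion variable escalates to the log, all three
phases are logged (rms and range values are strictly positive) — and
records the phases logged purely for consistency under a
`log_harmonized` provenance flag.

The battery mirrors the standard reporting for this design, all
two-sided, no multiplicity correction, pairwise-complete deletion:

* paired t tests across phase pairs (PT−S, S−RM, PT−RM; PT−AcuteThreat
  for fear codes), differences first-listed minus second;
* Pearson correlations of each phase's motion with the concurrent fear
  code (PT ↔ PT code; S, RM ↔ AcuteThreat code);
* Pearson correlations with CBCL Internalizing/Externalizing T scores,
  plus a Spearman screen against age and gender;
* independent-samples pooled-variance t tests between children with
  (past or current) and without an internalizing diagnosis, with
  pooled-SD Cohen's d, and a sensitivity rerun excluding externalizing
  disorders. The d is reported from the pooled-SD formula for every row;
  published effect-size columns in this literature are occasionally
  inconsistent with that formula, and no attempt is made to reproduce
  any other unnamed effect-size definition.

Exploratory linear/logistic fits over the cohort table are provided as a
thin `glm` wrapper (`fit_outcome()`) but deliberately sit outside the
validated battery.

## The synthetic cohort generator

Every stage is testable without any data download via a simulator that
emits exactly the CSV dialects the readers ingest. Torso motion is
modelled as band-limited random oscillations — sums of six
random-frequency sinusoids per channel — in tilt (slow wander
0.15–1 Hz plus a fast 1.4–2 Hz band), yaw (0.05–0.35 Hz wander plus a
0.8–2 Hz band) and world-frame translational sway (0.3–2 Hz), with
per-phase amplitude envelopes (raised-cosine transitions at the phase
boundaries), a constant mounting tilt, and a vertical half-sine startle
transient. Sensor signals are produced by *exact forward kinematics*
(rotating gravity into the sensor frame and emitting the true angular
rate), so closed-form fixtures (static, tilted, constant yaw rotation,
tilt/sway sinusoids) give analytically known features: rms of a
sinusoid \(= A/\sqrt 2\), rom \(= 2A\) (the tilt sinusoid oscillates
about a nonzero mean so the tilt angle never folds at zero), yaw at
20 deg/s for 5 s \(= 100°\).

Cohort structure: a per-subject latent factor \(z \sim N(0,1)\)
multiplies all amplitudes by \(e^{\sigma z}\) with \(\sigma = 0.45\),
chosen so the spread of the simulated descriptives matches the span of
published cohorts for this task. Diagnosed subjects (prevalence 21/61,
past:current 4:17) get an additional multiplicative Potential Threat
elevation \(e^{d\,\sigma}\) with \(d = 0.9\) — multiplicative in
amplitude, hence additive on the log scale where the statistics operate.
The externalizing T score couples to \(z\) through a Gaussian copula at
\(r = 0.45\); the Acute Threat fear score couples to \(z\) (which also
drives startle-phase motion) at \(r = 0.5\); the internalizing T score
is weakly coupled (\(r = 0.1\)); age and gender are independent.
Sample-size conditions default to the published design: 63 subjects, 7
without codeable video, 2 without clinical assessment. Amplitude
defaults were anchored once so that simulated per-phase descriptives
fall inside the published ranges (e.g. mean PT horizontal-acceleration
rms within 0.32–2.27 m/s²) and were not revisited.

Parameter recovery is defined on the log scale, where the generator
imposes its effects, using the horizontal-acceleration rms as index
variable: the diagnosis effect as pooled-SD d of log PT `ah_rms`; the
externalizing coupling as r of log RM `ah_rms` with the externalizing T
(RM rather than PT, because PT additionally carries the diagnosis shift,
which is noise for that correlation); the code coupling as r of log S
`ah_rms` with the Acute Threat score. Over 200 replicate cohorts at
n = 61 the mean recovered values sit within a few hundredths of the
configured 0.9 / 0.45 / 0.5 — the residual gap is the expected
attenuation from finite-window rms estimation noise on top of the
between-subject spread.

What the simulator does *not* emulate: real child biomechanics (gait,
posture changes, fidgeting spectra), video, physiological channels, or
any systematic relation between age/gender and motion. Passing tests
therefore demonstrate that the pipeline recovers known structure from
signals with the assumed statistical shape — not that real recordings
have that shape.

## Problem sizes and reproducibility

Default study conditions are 100 Hz × 52 s recordings; the bundled test
suite uses cohorts of 12–63 subjects and a 200-replicate recovery study
at n = 61, sizes chosen to estimate the recovery means to ±0.02 (standard
error) while keeping a full run in minutes on one core. All randomness
flows through R's default Mersenne-Twister generator from a single
configured seed; identical seeds give bit-identical cohorts, and the
analyze stage is byte-deterministic on unchanged inputs.

## Applying the pipeline to deposited data

The raw-CSV reader is schema-driven (column names and units are
configuration) because deposited files in this literature do not share a
dialect, and the pipeline equally accepts already-derived per-phase
feature tables (`read_feature_table()`, or `features_csv` in the
pipeline config), so a deposit containing either raw samples or derived
variables can be ingested. Reproducing a specific published table from a
specific deposit is then a configuration exercise — mapping its columns
and supplying its startle annotations — documented in the README as a
stretch goal; the package's own validation rests on the oracle fixtures
and the synthetic cohorts above.

## Known limitations

* Yaw is gyro-integrated; over very long windows its range acquires a
  slow random-walk component from gyro noise (negligible at the 20 s
  windows and noise levels here).
* The vertical estimate and hence \(a_h/a_v\) split is biased during
  sustained coherent sway (see above); between-subject contrasts are
  unaffected, absolute levels can be compressed by tens of percent
  depending on the sway spectrum and filter gain.
* The cleaning rule's log escalation requires strictly positive
  minima; zero-inflated variables stay winsorized-only by design.
* ICC is implemented for the two-coder design only.
* The effect-size column reports pooled-SD Cohen's d exclusively.
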