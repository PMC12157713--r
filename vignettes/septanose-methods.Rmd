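---
title: "Correcting the inspired-oxygen confounder in breath e-Nose classification"
author: "septanose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting the inspired-oxygen confounder in breath e-Nose classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septanose)
```

## The problem

Metal-oxide-semiconductor (MOS) gas-sensor arrays ("electronic noses") can
classify disease states from the pattern of volatile compounds (VCs) in
exhaled breath. In mechanically ventilated subjects there is a serious
confounder: the fraction of inspired oxygen (FiO2). N-type MOS sensors raise
their resistance as the oxygen content of the sample rises, and FiO2 is
adjusted upward precisely when a patient deteriorates — so oxygen content is
correlated with the condition one is trying to detect. A classifier trained
on raw sensor curves can look accurate while mostly reading the ventilator
setting.

`septanose` implements the full analysis pipeline for this setting —
ventilator-synchronized breath-sample collection logic, clean-air
calibration, bivariate FiO2 correction surfaces, curve-shape feature
extraction, and per-timepoint leave-one-out (LOO) classification of control
versus endotoxemic (LPS-challenged) subjects — together with a synthetic
generator that emulates the sensor physics and the cohort's physiology, so
every stage is testable without animal data.

## Measurement model

Each e-Nose analysis records, per channel, a resistance time series over
three phases: **before** (1 min; clean, humidified reference air — the
baseline), **during** (5 min; the bag sample flows through the sensor
chamber), and **after** (10 min; recovery in clean air). The default array
holds eight channels (two TGS2603, two TGS2600, and one each of TGS2610,
TGS2620, TGS2611, TGS2602); duplicated models are distinct physical channels
(`_a`/`_b`) because two units of one model need not respond identically.

The synthetic forward model is the minimal first-order model consistent with
the observed directionality. With $g(t)$ a first-order on/off envelope
(charge time constant $\tau_{on}$ in "during", decay $\tau_{off}$ in
"after", zero in "before"):

* additive oxygen mode:
  $R(t) = r_0\,[1 - \alpha v\, g(t)] + r_0\,\beta (F - 0.21)\, g(t)$
* multiplicative oxygen mode:
  $R(t) = r_0\,[1 - \alpha v\, g(t)]\,[1 + \beta (F - 0.21)\, g(t)]$

where $r_0$ is the baseline resistance, $v \ge 0$ the dimensionless VC load
($\alpha < 1$ its maximal fractional effect), $F$ the sample's FiO2 and
$\beta$ the oxygen sensitivity. Noise is multiplicative lognormal with unit
mean and coefficient of variation `noiseCv` (default 0.01 — the source data
quantify no sensor noise, so this is a documented assumption, not an
estimate). The two modes exist because they pair *exactly* with the two
correction strategies below, which gives the package its strongest oracle:
correction must collapse noise-free curves onto the reference-level VC-only
curve to machine precision.

## FiO2 correction surfaces

Calibration uses clean air (zero VC load) from a test lung at FiO2 levels
21, 25, 30, 35, 40, 50 % — three replicates per level, eighteen
measurements. For each channel the per-level mean curve $M(t, F)$ is formed
and the bivariate correction surface is

* $k_{diff}(t, F) = M(t, F) - M(t, 0.21)$, applied subtractively to
  subtract-baseline-removed sample curves $R(t) - R(0)$;
* $k_{ratio}(t, F) = M(t, F) / M(t, 0.21)$, applied by division to
  divide-baseline-removed sample curves $R(t)/R(0)$.

Design decisions worth stating:

* **Calibration baseline mode.** The correction is applied to
  baseline-removed sample curves, so by default the calibration mean curves
  are baseline-removed with the strategy's own mode *before* differencing or
  ratioing (`baselineMode = "matched"`), keeping $k$ in the sample curves'
  units and making $k_{diff}(0,\cdot)=0$, $k_{ratio}(0,\cdot)=1$. The
  literal raw-units construction is available via `baselineMode = "raw"`.
* **Strategy-2 denominator.** The ratio-corrected curve is divided by
  $k_{ratio}$, not $k_{diff}$; the two strategies never mix.
* **Interpolation and extrapolation.** Evaluation inside the (time × level)
  hull is bilinear. FiO2 outside [21, 50] % is clamped to the nearest
  calibrated level with a warning, because MOS–oxygen linearity beyond the
  characterized range is unsupported; times outside the calibration grid are
  an error. When sample and surface grids differ, the surface is resampled
  linearly in time — never the sample.
* **Reference identity.** At $F = 0.21$ both corrections are exact
  identities at every grid node, by construction.

## Features and outlier screening

Each (baseline-removed, optionally corrected) channel curve is reduced to
six features measured on the deviation from its start value: amplitude
(max |deviation|), area under |deviation| (trapezoidal), steepest negative
slope in "during", steepest positive slope in "after", time from "during"
onset to the extremum, and the recovery fraction at the end of "after". The
response amplitude, area and slope are the documented minimum; the on/off
kinetics complete a "shape and dynamics" description. Features are computed
after correction, matching the modeling order.

Outliers are screened per (timepoint, feature) with Tukey fences
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$. A literal
"outside the IQR" rule (fences at the quartiles, `fenceMult = 0`) would
discard about half of every cell group, so 1.5 is the default and the
literal rule remains selectable. Masked cells are imputed with the in-fence
median of their cell group rather than deleting the sample, keeping the LOO
design balanced. The exported `iqrScreen` iterates masking and fence
re-estimation to a fixpoint, which makes it idempotent; inside LOO folds a
single pass with training-fold statistics is used (test rows are screened
with fences learned on the training rows only, so no information leaks).

## Classification protocol

Two model families are evaluated at each post-baseline timepoint
(t5 … t180), with the data set assembled *cumulatively*: the model at t60
uses all samples from t5, t30 and t60. The pre-administration baseline t0 is
excluded (a flag can include it).

* **physio**: z-score → 5 principal components → logistic regression, on
  MAP, DBP, SBP, HR and temperature.
* **enose_raw / enose_kdiff / enose_kratio**: z-score → 2 principal
  components → depth-3 decision tree, on the curve features; the three
  variants differ only in the correction applied before feature extraction.

All transforms are fitted on training data only and applied to the test
fold. PCA loading signs are fixed by making each loading's
largest-magnitude element positive, so results are reproducible across
numerically equivalent decompositions.

Further choices the protocol text leaves open:

* **LOO unit.** The default held-out unit is the *animal*: with cumulative
  assembly an animal contributes several rows, and holding out single rows
  would leak a subject's identity into its own training set. `unit =
  "sample"` is available.
* **Balanced class priors.** Both classifiers train with balanced priors
  (case weights for the logistic model, `prior = c(0.5, 0.5)` for the
  tree). Under leave-one-animal-out the training fold is always depleted in
  the held-out animal's class — and the study groups are 9 vs 10 to begin
  with — so an empirical prior biases every held-out prediction toward the
  other class; on label-free data this collapses accuracy far below chance,
  which is a property of the evaluation design, not of the data.
* **Tree regularization.** rpart's defaults (`minsplit = 20`,
  `minbucket = 7`, `cp = 0.01`, Gini) with the depth cap, and `xval = 0`:
  internal cross-validation is not used by the pipeline and disabling it
  removes the only stochastic component of the fit.
* **Confidence intervals.** Metrics are reported as percents with 95 % Wald
  intervals $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$ clipped to [0, 100],
  the simplest method consistent with symmetric printed intervals; Wilson
  intervals are available. Zero-denominator metrics are reported missing,
  not zero.
* **Physiological trajectories.** For the physiological data an
  interpretable summary is also provided: z-score and PCA are fitted on t0
  records only, later records are projected into that fixed space, and each
  animal's displacement vector (modulus × direction) from its own t0 is
  averaged within groups.

## The synthetic cohort

`cohortSpec()` defaults emulate the study design: 9 control and 10 LPS
animals, eight timepoints (t0, t5, t30, t60, t90, t120, t150, t180), and a
group-correlated FiO2 policy — controls flat near 0.30, the LPS group
escalating after t30 up to 0.50 as oxygenation deteriorates. The VC load of
the LPS group rises monotonically with time since administration (the
endotoxin dose itself escalates stepwise); magnitudes are modelling
assumptions, as the source data publish no effect sizes. Physiology is drawn
around group trends — control MAP held above 80 mmHg, LPS MAP declining into
the 40–60 mmHg band, rising heart rate and temperature — and always
satisfies DBP ≤ MAP ≤ SBP. Per-measurement VC draws are independent
(no animal-level random effect by default), and all randomness flows from
the spec's single seed.

Three benchmark scenarios instantiate the properties the pipeline must have:

* `nullCohortSpec()` — zero VC effect, shared flat FiO2, identical
  physiology: labels carry no signal, and every variant's pooled LOO
  accuracy must stay at chance.
* `strongEffectCohortSpec()` — flat shared FiO2 and a rapid-onset VC
  schedule whose group separation exceeds five noise SDs at every
  post-baseline timepoint (a slow ramp would leave the early cumulative rows
  at chance and cap pooled accuracy below what a "strong effect" should
  achieve, no matter the classifier).
* `confoundedCohortSpec()` — zero VC effect with the group-coupled FiO2
  escalation: any e-Nose signal is pure oxygen confounding. The raw variant
  should look accurate late in the protocol while both corrected variants
  return to chance — the mechanism that motivates correcting at all.

What the generator does **not** emulate: chemically realistic VC mixtures,
humidity (the measurement protocol equalizes it; an explicit humidity term
is out of the acceptance path), bag storage deterioration, sensor drift
between calibration and cohort sessions, and animal-to-animal sensor
transfer effects. Passing the included tests therefore shows the algebra,
leakage control and calibration of the pipeline are right — not that any
particular accuracy is attainable on real animals.

## Numerical and statistical choices

* Quantiles use R's default type 7; medians for imputation are computed on
  in-fence values.
* The chance band used by the null-calibration check is the central 95 %
  binomial band around 50 % evaluated at the number of *independent LOO
  units* (animals). Within-animal predictions share a fold model, so a band
  at the number of pooled predictions would undercover by design — we
  measured ~85 % coverage — and would test the design effect of LOO rather
  than the calibration of the pipeline.
* Collapse residuals under noise are reported as RMS deviation from the
  reference VC-only curve, normalized by the RMS of the raw reference-level
  resistance curve, so the same definition serves both the subtractive and
  the divisive strategy.
* Exhalation detection opens a segment on the first sample strictly below
  the threshold after a sample at/above it and closes at the next sample
  at/above it; a 2-sample debounce (optional, default on) rejects isolated
  noise spikes without moving boundaries on clean waves. Truncated final
  segments are flagged, not dropped silently.
* Degenerate inputs: constant curves produce all-zero deviations and zero
  features; all-equal screening groups mask nothing; zero-SD feature columns
  z-score to 0 with a warning; training folds missing a class are flagged
  and excluded from pooling.

## Problem sizes

Unit tests run on a two-channel array with a shortened protocol (10/50/60 s
phases at 1 Hz). The cohort-scale batteries — null calibration (20 seeded
replicates of a 10+10 cohort), strong-effect recovery, confound
discrimination, and the end-to-end determinism check — run the full
eight-channel array at 0.5 Hz; the sensor model and all algebraic
identities are sampling-rate-agnostic, and the default 1 Hz remains the
package-wide default for data generation.

## Limitations

The forward model is separable and first-order; real MOS kinetics show
humidity-dependent sensitivity, power-law resistance–concentration laws and
hysteresis that the correction surfaces would only partially capture. The
correction is calibrated on clean air, so its validity on VC-loaded samples
rests on the separability assumption. LOO accuracy estimates on ~20 subjects
carry wide confidence intervals, and with cumulative assembly the pooled
predictions are not independent — both facts should temper any reading of
per-timepoint accuracy curves, synthetic or real.
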