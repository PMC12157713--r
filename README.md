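# septanose

Exhaled-breath electronic-nose (e-Nose) analysis for early sepsis detection
during mechanical ventilation, with explicit correction of the
inspired-oxygen (FiO2) confounder.

## The problem

Metal-oxide-semiconductor (MOS) gas sensors respond to the volatile
compounds (VCs) in exhaled breath, so an array of partially specific sensors
("smell print") can in principle flag a developing septic response before
physiological signs do. In ventilated subjects there is a catch: n-type MOS
resistance also rises with the oxygen content of the sample, and FiO2 is
escalated exactly when a subject deteriorates. A classifier on raw sensor
curves can therefore score well by reading the ventilator setting rather
than the breath chemistry.

`septanose` is intended for researchers analysing (or planning) breath
volatolomics studies in ventilated cohorts. It implements:

* **Breath-sampling logic** — simulation of the expiratory-line pressure
  waveform, threshold-based exhalation detection (with optional debounce)
  and bag-fill accounting for synchronized collection.
* **FiO2 correction surfaces** — from a clean-air calibration series at
  FiO2 levels 21–50 % (3 replicates per level), per-channel bivariate
  surfaces built from per-level mean curves `M(t, F)`:

  `k_diff(t, F) = M(t, F) − M(t, 0.21)` applied as
  `R_corr = [R(t) − R(0)] − k_diff(t, F)`, and

  `k_ratio(t, F) = M(t, F) / M(t, 0.21)` applied as
  `R_corr = [R(t)/R(0)] / k_ratio(t, F)`,

  evaluated by bilinear interpolation in (t, FiO2).
* **Feature extraction** — amplitude, area under the curve, on/off slopes,
  time-to-extremum and recovery fraction per channel, with Tukey-fence
  (IQR) outlier screening per timepoint and feature.
* **Per-timepoint classification** — cumulative data assembly (the model at
  t60 uses samples from t5, t30 and t60), leave-one-animal-out evaluation
  with in-fold z-score + PCA (+ in-fold outlier screen), logistic
  regression for the physiological model and a depth-3 decision tree for
  the e-Nose models, and accuracy / sensitivity / specificity with 95 %
  Wald confidence intervals.
* **A synthetic-data generator** — a first-order MOS forward model (VC load
  lowers resistance, oxygen raises it, additively or multiplicatively) plus
  cohort physiology (MAP/DBP/SBP, HR, temperature with group trends, and a
  group-correlated FiO2 escalation policy), so the whole pipeline is
  testable without animal data.

## Worked example

Simulate the default study-like cohort (9 control + 10 LPS animals, FiO2
escalating in the LPS group), build the calibration series, and evaluate
all four model variants at two timepoints:

```r
library(septanose)

models <- defaultSensorModels()
cal    <- simulateCalibrationSeries(models, seed = 99, rateHz = 0.5)
co     <- simulateCohort(cohortSpec(seed = 42), models, rateHz = 0.5)
study  <- runStudy(co$measurements, co$physio, cal,
                   timepoints = c("t60", "t120"), seed = 42)
subset(study$results, metric == "accuracy")
```

```
      variant timepoint   metric value ci_lo ci_hi  n
       physio       t60 accuracy  84.2  74.7  93.7 57
       physio      t120 accuracy  88.4  82.0  94.9 95
    enose_raw       t60 accuracy  61.4  48.8  74.0 57
    enose_raw      t120 accuracy  68.4  59.1  77.8 95
  enose_kdiff       t60 accuracy  77.2  66.3  88.1 57
  enose_kdiff      t120 accuracy  82.1  74.4  89.8 95
 enose_kratio       t60 accuracy  78.9  68.4  89.5 57
 enose_kratio      t120 accuracy  85.3  78.1  92.4 95
```

Each row is one model variant at one timepoint: `value` is the pooled
leave-one-animal-out accuracy in percent over the `n` cumulative samples
(19 animals × the timepoints up to the target), with its 95 % Wald interval.
In this synthetic cohort both a real VC effect and the FiO2 confound are
present; the corrected e-Nose variants (`enose_kdiff`, `enose_kratio`)
outperform the uncorrected curves because the within-group FiO2 variability
is removed before feature extraction.

The one-shot pipeline (simulate → calibrate → correct → featurize →
train-eval → report, with every intermediate persisted and a config echo)
is:

```r
runAll(demoRunConfig(outDir = "demo_run", seed = 1))
read.csv("demo_run/results.csv")   # variant, timepoint, metric, value, ci_lo, ci_hi, n
```

A thin command-line wrapper with `simulate`, `calibrate`, `sample-sim` and
`run-all` subcommands is installed at
`system.file("scripts", "septanose-cli.R", package = "septanose")`.

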