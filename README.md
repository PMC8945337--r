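# filmsense

Psychophysiological characterization of caffeine oral films from
multimodal signal energy.

Orodispersible films are polymer strips that dissolve in the mouth and
release an active compound — here caffeine, partly microencapsulated for
sustained release. Instead of blood sampling, the delivery profile can
be read out non-invasively from autonomic signals: the electrocardiogram
(ECG), electrodermal activity (EDA) and respiration (RF). `filmsense`
implements that time-signal-energy analysis as a tested R pipeline and,
because no real recordings are distributed, pairs it with a first-class
synthetic-cohort generator whose caffeine effect follows a
dual-compartment Bateman absorption–elimination profile,

    C(t) = D * ka/(ka - ke) * (exp(-ke t) - exp(-ka t)),

summed over a fast free fraction and a slow encapsulated fraction.

The analysis chain: per-modality linear-phase FIR filtering (EDA
low-pass 1 Hz, RF low-pass 3 Hz, ECG band-pass 1–30 Hz), whole-record
amplitude normalization and mean removal, 5-minute segmentation with
signal power energy `EN = sum(|x(n)|^2)` over 5-second rectangular
windows, per-segment group-mean profiles (10 points per group for a
50-minute session) jointly z-scored, and leave-one-out cross-validated
discrimination of caffeine vs. placebo by a bank of eleven binary
classifiers (decision trees, polynomial-kernel SVMs, cosine/cubic KNN,
discriminant analysis, logistic regression, and an ROC-threshold
classifier, "XROC").

## Worked example

Simulate a six-subject within-subject study (each volunteer recorded
once with a caffeine film and once with a placebo film), run the whole
pipeline, and print the accuracy table:

```r
library(filmsense)

cfg <- cohort_config(n_subjects = 6, duration = 50, fs = 64, seed = 42)
res <- run_study(study_config(cohort = cfg))
res
#> <study_result>
#>   seed 42 | 6 subjects | 50 min @ 64 Hz
#>   classifier accuracy table (%):
#>              classifier             optimal_parameters acc_ecg acc_eda acc_rf
#>               Fine Tree Maximum number of splits = 150     100      50     50
#>             Medium Tree Maximum number of splits = 150     100      50     50
#>       SVM Linear Kernel       Box constraint level = 5     100      75     60
#>    SVM Quadratic Kernel       Box constraint level = 3     100      75     70
#>        SVM Cubic Kernel       Box constraint level = 2     100      70     65
#>              Cosine KNN        Number of neighbors = 3     100      75     65
#>               Cubic KNN        Number of neighbors = 3     100      65     65
#>     Discriminant Linear     Covariance structure: Full     100      75     65
#>                Logistic     Covariance structure: Full     100      75     65
#>  Discriminant Quadratic     Covariance structure: Full     100      75     65
#>                    XROC                              -     100      65     75

round(bank_mean_accuracy(res), 1)
#>   ecg   eda    rf
#> 100.0  68.2  63.2
```

Each accuracy is the percentage of correct leave-one-out folds over the
20 z-scored group-mean energy points (10 caffeine, 10 placebo) of that
modality. ECG separates perfectly — the heart-rate gain couples directly
to windowed energy — while EDA is intermediate and respiration hovers
near chance, because a breathing-*rate* change barely moves signal
energy. Averaged over many seeds the bank means are approximately
ECG 100 / EDA 77 / RF 46 percent (single seeds fluctuate, as above).

Individual stages are exported: `generate_cohort()`, `filter_signal()`,
`normalize_amplitude()`, `segment_signal()`, `window_energy()`,
`zscore_joint()`, `loocv()`, `train_xroc()`, `run_classifier_bank()`.
Records round-trip through CSV (lossless) and a minimal single-signal
EDF (16-bit, quantization-bounded) via `write_recording()` /
`read_recording()`. A thin command-line wrapper with `synth` and `run`
subcommands is installed at `inst/scripts/filmsense`.

See the methods vignette (`vignettes/filmsense-methods.Rmd`) for the
model, the normalization-mode decision, generator calibration, and
limitations.

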