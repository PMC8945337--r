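# Shared fixture builders; everything is generated in code.

# A quiet subject for deterministic signal-math checks.
quiet_subject <- function(...) {
  subject_params(hrv_sd = 0, ecg_noise_sd = 0, eda_drift_sd = 0,
                 eda_noise_sd = 0, resp_amp_sd = 0, resp_noise_sd = 0,
                 ...)
}

# Small cohort for pipeline-level tests: short session, low rate.
small_cohort <- function(seed = 1, ...) {
  cohort_config(n_subjects = 2, duration = 10, fs = 64, seed = seed, ...)
}

# Balanced 1-D two-class dataset.
random_points <- function(n_per_class = 10, sep = 1, noise = 0.5) {
  labeled_points(
    c(rnorm(n_per_class, -sep, noise), rnorm(n_per_class, sep, noise)),
    rep(c("placebo", "caffeine"), each = n_per_class))
}
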