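test_that("ECG synthesis places the expected number of beats", {
  fs <- 250
  s <- quiet_subject(hr_baseline = 60)
  rec <- simulate_ecg(5, fs, s, rep(0, 5 * 60 * fs), seed = 1)
  expect_length(rec$samples, 5 * 60 * fs)
  expect_identical(rec$modality, "ECG")
  # R peaks of the noise-free template counted as upward 0.5 mV crossings
  x <- rec$samples
  peaks <- sum(x[-1] >= 0.5 & x[-length(x)] < 0.5)
  expect_gte(peaks, 294)
  expect_lte(peaks, 306)
})

test_that("simulators are bit-reproducible and validate their inputs", {
  fs <- 100
  s <- subject_params()
  eff <- rep(0.5, 2 * 60 * fs)
  for (sim in list(simulate_ecg, simulate_eda, simulate_resp)) {
    a <- sim(2, fs, s, eff, seed = 7)
    b <- sim(2, fs, s, eff, seed = 7)
    expect_identical(a$samples, b$samples)
    expect_error(sim(2, fs, s, eff[-1], seed = 7), "effect array")
  }
})

test_that("EDA output is nonnegative with Poisson-calibrated SCR counts", {
  fs <- 32
  s <- subject_params(scr_rate = 3)
  eff <- rep(0, 10 * 60 * fs)
  counts <- vapply(1:200, function(k)
    attr(simulate_eda(10, fs, s, eff, seed = 1000 + k), "n_scr"),
    numeric(1))
  # expectation 3/min * 10 min = 30
  expect_gt(mean(counts), 30 * 0.85)
  expect_lt(mean(counts), 30 * 1.15)
  rec <- simulate_eda(10, fs, s, eff, seed = 5)
  expect_true(all(rec$samples >= 0))
})

test_that("terminal electrode artifact inflates the final segment energy", {
  fs <- 64
  s <- subject_params()
  eff <- rep(0, 20 * 60 * fs)
  rec <- simulate_eda(20, fs, s, eff, seed = 9,
                      artifact_final_segment = TRUE)
  en <- record_segment_energies(rec)
  expect_gt(en[length(en)], mean(en[-length(en)]))
})

test_that("respiration has the configured dominant frequency", {
  fs <- 50
  s <- quiet_subject(resp_rate = 15)
  rec <- simulate_resp(5, fs, s, rep(0, 5 * 60 * fs), seed = 3)
  n <- length(rec$samples)
  spec <- Mod(fft(rec$samples))[seq_len(n %/% 2)]
  f_peak <- (which.max(spec) - 1) * fs / n
  expect_equal(f_peak, 15 / 60, tolerance = fs / n + 1e-9)
})

test_that("a positive effect raises the instantaneous breathing rate", {
  fs <- 50
  s <- quiet_subject(resp_rate = 15)
  n <- 5 * 60 * fs
  base <- simulate_resp(5, fs, s, rep(0, n), seed = 3)
  fast <- simulate_resp(5, fs, s, rep(1, n), seed = 3)
  zc <- function(x) sum(x[-1] >= 0 & x[-length(x)] < 0)
  expect_gt(zc(fast$samples), zc(base$samples))
})

test_that("cohort generation is labelled, sized and placebo-invariant", {
  cfg <- cohort_config(n_subjects = 13, duration = 10, fs = 64, seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh, 78)  # 13 subjects x 3 modalities x 2 conditions
  mods <- vapply(coh, `[[`, character(1), "modality")
  conds <- vapply(coh, `[[`, character(1), "condition")
  expect_equal(unname(table(mods)), rep(26L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(conds)), rep(39L, 2), ignore_attr = TRUE)

  cfg2 <- cohort_config(n_subjects = 2, duration = 10, fs = 100, seed = 2)
  coh2 <- generate_cohort(cfg2)
  expect_true(all(vapply(coh2, function(r) length(r$samples), numeric(1))
                  == 60000))

  # placebo records do not depend on the caffeine doses
  cfg_hi <- cohort_config(n_subjects = 2, duration = 10, fs = 64, seed = 5,
                          pk = pk_profile(dose_free = 5,
                                          dose_encapsulated = 5))
  cfg_lo <- cohort_config(n_subjects = 2, duration = 10, fs = 64, seed = 5,
                          pk = pk_profile(dose_free = 0.1,
                                          dose_encapsulated = 0.1))
  a <- generate_cohort(cfg_hi)
  b <- generate_cohort(cfg_lo)
  plc <- grep("placebo", names(a), value = TRUE)
  for (key in plc) expect_identical(a[[key]]$samples, b[[key]]$samples)
})

test_that("cohorts are bit-reproducible and subjects have stable streams", {
  cfg <- small_cohort(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # adding a subject never perturbs existing subjects
  cfg3 <- cohort_config(n_subjects = 3, duration = 10, fs = 64, seed = 11)
  c3 <- generate_cohort(cfg3)
  for (key in names(a)) expect_identical(a[[key]]$samples,
                                         c3[[key]]$samples)
})

test_that("raising the dose raises mid-session caffeine energy (ECG, EDA)", {
  fs <- 64
  n <- 20 * 60 * fs
  t_min <- (seq_len(n) - 1) / (fs * 60)
  s <- quiet_subject()
  mid <- function(rec) {
    en <- record_segment_energies(rec)
    mean(en[2:3])
  }
  doses <- c(0, 1, 2)
  for (sim in list(simulate_ecg, simulate_eda)) {
    mids <- vapply(doses, function(d) {
      pk <- if (d == 0) pk_placebo() else
        pk_profile(dose_free = 0.6 * d, dose_encapsulated = 0.8 * d)
      mid(sim(20, fs, s, effect_profile(t_min, pk), seed = 4))
    }, numeric(1))
    expect_true(all(diff(mids) > 0))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(duration = 5), "duration")
  expect_error(cohort_config(fs = 50), "fs")
  expect_error(subject_params(hr_baseline = 30), "hr_baseline")
  expect_error(subject_params(resp_rate = 40), "resp_rate")
  expect_error(subject_params(effect_gains = c(alpha_ecg = -1,
                                               beta_eda_tonic = 0,
                                               gamma_scr = 0,
                                               delta_resp = 0)),
               "gains")
})
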