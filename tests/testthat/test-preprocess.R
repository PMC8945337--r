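test_that("default FIR designs meet their band specifications", {
  fs <- 1000

  eda <- design_fir(filter_spec("EDA"), fs)
  expect_gte(fir_response(eda, 0.1, fs), 0.99)
  expect_lte(fir_response(eda, 5, fs), 0.01)

  ecg <- design_fir(filter_spec("ECG"), fs)
  # within 0.5 dB of unity in mid-band
  expect_lt(abs(20 * log10(fir_response(ecg, 10, fs))), 0.5)

  # -6 dB (within 1 dB) at every cutoff
  for (spec in list(filter_spec("EDA"), filter_spec("RF"),
                    filter_spec("ECG"))) {
    h <- design_fir(spec, fs)
    for (fc in spec$cutoffs) {
      db <- 20 * log10(fir_response(h, fc, fs))
      expect_gt(db, -7)
      expect_lt(db, -5)
    }
  }
})

test_that("FIR coefficients are symmetric (linear phase)", {
  for (m in c("ECG", "EDA", "RF")) {
    h <- design_fir(filter_spec(m), 500)
    expect_equal(as.numeric(h), rev(as.numeric(h)), tolerance = 1e-12)
  }
})

test_that("filter design rejects cutoffs at or above Nyquist", {
  expect_error(design_fir(filter_spec("ECG"), 60), "Nyquist")
  expect_error(filter_spec("ECG", cutoffs = c(30, 1)), "increasing")
  expect_error(filter_spec("EDA", cutoffs = -1), "positive")
})

test_that("zero-phase filtering passes and stops the right bands", {
  fs <- 500
  t <- seq(1 / fs, 40, by = 1 / fs)
  spec <- filter_spec("ECG")
  ord <- attr(design_fir(spec, fs), "order")

  inband <- signal_record(sin(2 * pi * 10 * t), fs, "ECG")
  y <- filter_signal(inband, spec)
  interior <- (2 * ord):(length(t) - 2 * ord)
  expect_equal(sd(y$samples[interior]), sd(inband$samples[interior]),
               tolerance = 0.02)

  outband <- signal_record(sin(2 * pi * 0.1 * t), fs, "ECG")
  y2 <- filter_signal(outband, spec)
  expect_lt(sqrt(mean(y2$samples^2)) / sqrt(mean(outband$samples^2)),
            0.05)

  zeros <- signal_record(rep(0, length(t)), fs, "ECG")
  expect_equal(filter_signal(zeros, spec)$samples, rep(0, length(t)))
})

test_that("zero-phase filtering does not shift an interior pulse peak", {
  fs <- 200
  n <- 20000
  x <- rep(0, n)
  ctr <- 9500
  x[(ctr - 400):(ctr + 400)] <- dnorm(seq(-4, 4, length.out = 801))
  rec <- signal_record(x, fs, "RF")
  y <- filter_signal(rec, filter_spec("RF"))
  expect_equal(which.max(y$samples), ctr)
})

test_that("single-pass mode compensates the linear-phase group delay", {
  fs <- 200
  n <- 20000
  x <- rep(0, n)
  ctr <- 9500
  x[(ctr - 400):(ctr + 400)] <- dnorm(seq(-4, 4, length.out = 801))
  rec <- signal_record(x, fs, "RF")
  y <- filter_signal(rec, filter_spec("RF", phase_mode = "single-pass"))
  expect_equal(which.max(y$samples), ctr)
})

test_that("filtering rejects signals shorter than three filter orders", {
  rec <- signal_record(rnorm(1000), 1000, "ECG")
  expect_error(filter_signal(rec), "3 x filter order")
})

test_that("filtered output is finite for finite input", {
  set.seed(1)
  rec <- signal_record(rnorm(5000, sd = 100), 200, "EDA")
  y <- filter_signal(rec)
  expect_true(all(is.finite(y$samples)))
})

test_that("unit-energy normalization scales to unit energy then centers", {
  set.seed(2)
  x <- rnorm(512) + 3
  rec <- signal_record(x, 64, "EDA")
  out <- normalize_amplitude(rec)
  scaled <- x / sqrt(sum(x^2))
  expect_equal(sum(scaled^2), 1, tolerance = 1e-12)
  expect_equal(out$samples, scaled - mean(scaled), tolerance = 1e-12)

  # invariant to positive rescaling of the input
  out2 <- normalize_amplitude(signal_record(37.5 * x, 64, "EDA"))
  expect_equal(out$samples, out2$samples, tolerance = 1e-12)

  # re-normalizing changes nothing beyond the mean-removal interaction
  twice <- normalize_amplitude(
    signal_record(out$samples, 64, "EDA", units = "normalized"))
  energy <- sum(out$samples^2)
  expect_equal(twice$samples, out$samples / sqrt(energy) -
                 mean(out$samples / sqrt(energy)), tolerance = 1e-9)
})

test_that("literal normalization divides by the total energy as printed", {
  rec <- signal_record(c(1, 1), 10, "ECG")
  out <- normalize_amplitude(rec, mode = "literal")
  # sum(x^2) = 2 scales (1, 1) to (0.5, 0.5); centering gives (0, 0)
  expect_equal(out$samples, c(0, 0))
  expect_error(normalize_amplitude(signal_record(c(0, 0), 10, "ECG")),
               "zero energy")
})
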