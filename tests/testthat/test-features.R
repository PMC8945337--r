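test_that("segmentation follows the floor rule", {
  fs <- 20
  rec50 <- signal_record(rnorm(50 * 60 * fs), fs, "ECG")
  expect_length(segment_signal(rec50), 10)

  rec483 <- signal_record(rnorm(round(48.3 * 60 * fs)), fs, "ECG")
  expect_message(segs <- segment_signal(rec483), "dropping")
  expect_length(segs, 9)
  expect_equal(attr(segs, "dropped_s"), 3.3 * 60, tolerance = 1e-6)

  rec4 <- signal_record(rnorm(4 * 60 * fs), fs, "ECG")
  expect_error(segment_signal(rec4), "at least 5 min")
})

test_that("window energy sums squared samples over rectangular windows", {
  en <- window_energy(rep(1, 3000), fs = 100, window_s = 5)
  expect_length(en, 6)
  expect_true(all(as.numeric(en) == 500))

  expect_equal(as.numeric(window_energy(rep(0, 1000), 100)), rep(0, 2))

  # sinusoid over whole periods: EN ~ A^2 N / 2
  fs <- 100
  a <- 2.5
  x <- a * sin(2 * pi * 2 * seq(1, 3000) / fs)  # 2 Hz, 10 cycles/window
  en <- window_energy(x, fs, window_s = 5)
  expect_equal(as.numeric(en), rep(a^2 * 500 / 2, 6), tolerance = 0.01)

  expect_error(window_energy(rnorm(10), fs = 100, window_s = 5),
               "shorter than one window")
})

test_that("window energies account for total segment energy exactly", {
  set.seed(3)
  x <- rnorm(3210)
  fs <- 100
  en <- window_energy(x, fs, window_s = 5)
  remainder <- x[3001:3210]
  expect_equal(sum(as.numeric(en)) + sum(remainder^2), sum(x^2),
               tolerance = 1e-12)
  expect_true(all(as.numeric(en) >= 0))
})

test_that("segment mean energy is the arithmetic mean", {
  expect_equal(segment_mean_energy(c(1, 2, 3)), 2)
  expect_equal(segment_mean_energy(5), 5)
  expect_error(segment_mean_energy(numeric(0)), "empty")
})

test_that("group profiles average subjects symmetrically", {
  m <- rbind(c(2, 4, 6), c(4, 6, 8))
  p <- group_mean_profile(m, "caffeine")
  expect_equal(p$points, c(3, 5, 7))
  expect_false(p$zscored)

  # permutation invariance
  p2 <- group_mean_profile(m[2:1, ], "caffeine")
  expect_equal(p$points, p2$points)

  # one subject: the profile is that subject's means
  expect_equal(group_mean_profile(m[1, , drop = FALSE],
                                  "placebo")$points, c(2, 4, 6))

  # ragged input is truncated to the common minimum
  p3 <- group_mean_profile(list(c(1, 2, 3, 4), c(3, 4, 5)), "placebo")
  expect_equal(p3$points, c(2, 3, 4))
})

test_that("joint z-scoring pools both groups", {
  a <- group_mean_profile(matrix(rep(0, 5), 1), "placebo")
  b <- group_mean_profile(matrix(rep(2, 5), 1), "caffeine")
  z <- zscore_joint(a, b)
  expect_equal(z[[1]]$points, rep(-1, 5), tolerance = 1e-12)
  expect_equal(z[[2]]$points, rep(1, 5), tolerance = 1e-12)
  expect_true(z[[1]]$zscored && z[[2]]$zscored)

  set.seed(4)
  a <- group_mean_profile(matrix(runif(10), 1), "caffeine")
  b <- group_mean_profile(matrix(runif(10) + 0.3, 1), "placebo")
  z <- zscore_joint(a, b)
  pooled <- c(z[[1]]$points, z[[2]]$points)
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(pooled^2)), 1, tolerance = 1e-9)
  # between-group ordering of every pair of points is preserved
  expect_equal(sign(outer(a$points, b$points, `-`)),
               sign(outer(z[[1]]$points, z[[2]]$points, `-`)))

  # location invariance
  a2 <- group_mean_profile(matrix(a$points + 100, 1), "caffeine")
  b2 <- group_mean_profile(matrix(b$points + 100, 1), "placebo")
  z2 <- zscore_joint(a2, b2)
  expect_equal(z2[[1]]$points, z[[1]]$points, tolerance = 1e-9)

  # degenerate pooled spread
  c1 <- group_mean_profile(matrix(rep(1, 4), 1), "caffeine")
  c2 <- group_mean_profile(matrix(rep(1, 4), 1), "placebo")
  expect_error(zscore_joint(c1, c2), "standard deviation is zero")
})

test_that("caffeine raises raw mid-session energies before z-scoring", {
  # noise-free cohort: group-level check through the feature path
  fs <- 64
  n <- 20 * 60 * fs
  t_min <- (seq_len(n) - 1) / (fs * 60)
  eff <- effect_profile(t_min, pk_profile())
  s <- quiet_subject()
  for (sim in list(simulate_ecg, simulate_eda)) {
    caf <- record_segment_energies(sim(20, fs, s, eff, seed = 6,
                                       condition = "caffeine"))
    plc <- record_segment_energies(sim(20, fs, s, 0 * eff, seed = 6))
    expect_true(all(caf[2:4] > plc[2:4]))
  }
})
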