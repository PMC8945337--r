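bank_families <- names(classifier_bank())

test_that("well-separated classes give 100% for every family", {
  set.seed(10)
  pts <- random_points(10, sep = 1, noise = 0.1)
  for (fam in bank_families) {
    res <- loocv(pts, classifier_spec(fam))
    expect_equal(res$accuracy, 100,
                 info = paste("family:", fam))
  }
})

test_that("a constant feature sends majority-vote families to 0%", {
  pts <- labeled_points(rep(1, 20),
                        rep(c("placebo", "caffeine"), each = 10))
  for (fam in c("fine_tree", "medium_tree", "knn_cosine", "knn_cubic")) {
    # in every fold the opposite class holds the training majority
    expect_equal(loocv(pts, classifier_spec(fam))$accuracy, 0,
                 info = paste("family:", fam))
  }
})

test_that("LOOCV matches an independent brute-force oracle", {
  set.seed(42)
  n_datasets <- 12
  for (d in seq_len(n_datasets)) {
    sep <- runif(1, 0, 1.5)
    x <- c(rnorm(10, -sep, 1), rnorm(10, sep, 1))
    labs <- rep(c("placebo", "caffeine"), each = 10)
    pts <- labeled_points(x, labs)
    for (fam in bank_families) {
      expect_identical(loocv(pts, classifier_spec(fam))$accuracy,
                       oracle_loocv_accuracy(x, labs, fam),
                       info = sprintf("dataset %d family %s", d, fam))
    }
  }
})

test_that("the threshold classifier recovers the max-margin separator", {
  tr <- labeled_points(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                       c("A", "A", "A", "B", "B", "B"))
  m <- train_xroc(tr)
  expect_equal(m$threshold, 0.5)
  expect_equal(m$polarity, 1)  # values >= 0.5 -> second level ("B")
  expect_equal(as.character(predict_xroc(m, matrix(0.4))), "A")
  expect_equal(m$train_accuracy, 100)

  # swapping labels keeps the threshold and flips the polarity
  tr2 <- labeled_points(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                        c("B", "B", "B", "A", "A", "A"))
  m2 <- train_xroc(tr2)
  expect_equal(m2$threshold, 0.5)
  expect_equal(m2$polarity, -1)

  # identical feature values: no threshold, majority prediction
  tr3 <- labeled_points(rep(1, 5), c("A", "A", "B", "B", "B"))
  m3 <- train_xroc(tr3)
  expect_s3_class(m3, "filmsense_majority")
  expect_equal(as.character(
    filmsense:::predict_one(m3, matrix(c(0, 2), ncol = 1))), c("B", "B"))

  expect_error(train_xroc(labeled_points(matrix(rnorm(20), ncol = 2),
                                         rep(c("A", "B"), 5))),
               "scalar")
})

test_that("shuffled labels give chance-level mean accuracy", {
  set.seed(99)
  x <- rnorm(20)
  for (fam in c("xroc", "knn_cubic")) {
    accs <- vapply(1:200, function(k) {
      labs <- sample(rep(c("placebo", "caffeine"), each = 10))
      loocv(labeled_points(x, labs), classifier_spec(fam))$accuracy
    }, numeric(1))
    expect_gt(mean(accs), 35)
    expect_lt(mean(accs), 65)
  }
})

test_that("LOOCV is deterministic and reports per-fold predictions", {
  set.seed(5)
  pts <- random_points(8, sep = 0.4, noise = 0.6)
  a <- loocv(pts, classifier_spec("svm_quadratic"))
  b <- loocv(pts, classifier_spec("svm_quadratic"))
  expect_identical(a, b)
  expect_length(a$per_fold_predictions, 16)
  expect_equal(a$accuracy,
               100 * mean(a$per_fold_predictions == pts$labels),
               tolerance = 1e-12)
})

test_that("the bank table has the canonical layout", {
  set.seed(6)
  pts <- random_points(5, sep = 1, noise = 0.2)
  tab <- run_classifier_bank(list(ECG = pts, EDA = pts, RF = pts))
  expect_equal(nrow(tab), 11)
  expect_equal(names(tab), c("classifier", "optimal_parameters",
                             "acc_ecg", "acc_eda", "acc_rf"))
  expect_equal(tab$classifier[1], "Fine Tree")
  expect_equal(tab$classifier[11], "XROC")
  expect_equal(tab$optimal_parameters[3], "Box constraint level = 5")
  # identical inputs under different modality names: identical columns
  expect_equal(tab$acc_ecg, tab$acc_eda)
  expect_equal(tab$acc_ecg, tab$acc_rf)
})

test_that("labeled_points validates its inputs", {
  expect_error(labeled_points(1:4, c("a", "a", "a", "b")),
               "at least two points")
  expect_error(labeled_points(1:4, rep("a", 4)), "two classes")
  expect_error(labeled_points(c(1, NA, 2, 3), rep(c("a", "b"), 2)),
               "finite")
})
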