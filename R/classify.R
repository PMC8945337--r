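#' Labelled feature points for binary discrimination
#'
#' @param features Numeric vector (one-dimensional features) or matrix
#'   (points in rows). In the headline experiment each point is one
#'   z-scored per-segment group-mean energy, so the feature space is
#'   one-dimensional with 10 points per class.
#' @param labels Character or factor of class labels (`"caffeine"` /
#'   `"placebo"`), one per point; exactly two levels.
#' @return An object of class `labeled_points`.
#' @export
labeled_points <- function(features, labels) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop("labeled_points: features must be finite", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labeled_points: exactly two classes are required", call. = FALSE)
  if (length(labels) != nrow(features))
    stop("labeled_points: one label per feature row is required",
         call. = FALSE)
  if (any(table(labels) < 2))
    stop("labeled_points: each class needs at least two points for ",
         "leave-one-out cross-validation", call. = FALSE)
  structure(list(features = features, labels = labels),
            class = "labeled_points")
}

#' Classifier specification
#'
#' One entry of the classifier bank, with the hyperparameters fixed by the
#' study protocol: decision trees capped at 150 splits; soft-margin
#' (box-constraint) penalties of 5, 3 and 2 for the linear, quadratic and
#' cubic polynomial SVM kernels; 3 nearest neighbors for the cosine- and
#' cubic-(Minkowski exponent 3) distance KNN; full covariance structure
#' for the discriminant classifiers; and a reconstructed ROC-threshold
#' classifier (`xroc`) that picks the training-accuracy-optimal scalar
#' threshold and polarity.
#'
#' @param family One of `"fine_tree"`, `"medium_tree"`, `"svm_linear"`,
#'   `"svm_quadratic"`, `"svm_cubic"`, `"knn_cosine"`, `"knn_cubic"`,
#'   `"lda"`, `"logistic"`, `"qda"`, `"xroc"`.
#' @param ... Named hyperparameter overrides (`max_splits`, `cost`,
#'   `degree`, `k`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("fine_tree", "medium_tree",
                                       "svm_linear", "svm_quadratic",
                                       "svm_cubic", "knn_cosine",
                                       "knn_cubic", "lda", "logistic",
                                       "qda", "xroc"), ...) {
  family <- match.arg(family)
  hp <- switch(family,
    fine_tree = list(max_splits = 150),
    medium_tree = list(max_splits = 150),
    svm_linear = list(cost = 5, degree = 1),
    svm_quadratic = list(cost = 3, degree = 2),
    svm_cubic = list(cost = 2, degree = 3),
    knn_cosine = list(k = 3, distance = "cosine"),
    knn_cubic = list(k = 3, distance = "minkowski3"),
    lda = list(),
    logistic = list(),
    qda = list(),
    xroc = list())
  dots <- list(...)
  hp[names(dots)] <- dots
  structure(list(family = family, hyperparameters = hp),
            class = "classifier_spec")
}

#' The full classifier bank
#'
#' The eleven classifiers compared in the study, in their canonical order,
#' with display names and the hyperparameter summary used in the results
#' table.
#'
#' @return Named list of entries, each with `name`, `optimal_parameters`
#'   and `spec` ([classifier_spec()]).
#' @export
classifier_bank <- function() {
  entry <- function(name, params, family)
    list(name = name, optimal_parameters = params,
         spec = classifier_spec(family))
  list(
    fine_tree = entry("Fine Tree", "Maximum number of splits = 150",
                      "fine_tree"),
    medium_tree = entry("Medium Tree", "Maximum number of splits = 150",
                        "medium_tree"),
    svm_linear = entry("SVM Linear Kernel", "Box constraint level = 5",
                       "svm_linear"),
    svm_quadratic = entry("SVM Quadratic Kernel",
                          "Box constraint level = 3", "svm_quadratic"),
    svm_cubic = entry("SVM Cubic Kernel", "Box constraint level = 2",
                      "svm_cubic"),
    knn_cosine = entry("Cosine KNN", "Number of neighbors = 3",
                       "knn_cosine"),
    knn_cubic = entry("Cubic KNN", "Number of neighbors = 3", "knn_cubic"),
    lda = entry("Discriminant Linear", "Covariance structure: Full",
                "lda"),
    logistic = entry("Logistic", "Covariance structure: Full", "logistic"),
    qda = entry("Discriminant Quadratic", "Covariance structure: Full",
                "qda"),
    xroc = entry("XROC", "-", "xroc"))
}

# ---- internal fitting / prediction ----------------------------------------

# Majority model: deterministic fallback used when a training fold has a
# single class or a family's fit degenerates (e.g. zero within-class
# variance for QDA). Ties break to the first factor level.
fit_majority <- function(labels) {
  tab <- table(labels)
  structure(list(level = names(tab)[which.max(tab)],
                 levels = levels(labels)),
            class = "filmsense_majority")
}

predict_majority <- function(model, newdata) {
  factor(rep(model$level, nrow(newdata)), levels = model$levels)
}

knn_distances <- function(train_x, test_row, distance) {
  if (distance == "cosine") {
    nt <- sqrt(rowSums(train_x^2))
    nq <- sqrt(sum(test_row^2))
    d <- rep(1, nrow(train_x))
    ok <- nt > 0 & nq > 0
    d[ok] <- 1 - (train_x[ok, , drop = FALSE] %*% test_row) / (nt[ok] * nq)
    as.numeric(d)
  } else {
    (rowSums(abs(sweep(train_x, 2, test_row))^3))^(1 / 3)
  }
}

predict_knn <- function(model, newdata) {
  out <- character(nrow(newdata))
  k <- min(model$k, nrow(model$x))
  for (i in seq_len(nrow(newdata))) {
    d <- knn_distances(model$x, newdata[i, ], model$distance)
    # all points tied with the k-th smallest distance take part in the
    # vote, so all-equal distances degenerate to a training-majority vote
    nb <- which(d <= sort(d)[k])
    votes <- table(model$y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      out[i] <- top
    } else {
      # vote tie: class with the smaller summed neighbor distance,
      # then the first factor level
      sums <- vapply(top, function(lv) sum(d[nb][model$y[nb] == lv]),
                     numeric(1))
      out[i] <- top[order(sums, match(top, levels(model$y)))[1]]
    }
  }
  factor(out, levels = levels(model$y))
}

#' Train the ROC-threshold (XROC) classifier
#'
#' Scalar-threshold binary classifier: every midpoint between adjacent
#' sorted training values is tried with both polarities, and the pair with
#' the highest training accuracy (equivalently, the largest Youden J on
#' the empirical ROC) is kept. Ties are broken in favor of the threshold
#' with the largest margin to its nearest training values, then the
#' smaller threshold. If all training values are identical there is no
#' separating threshold and the classifier degenerates to
#' training-majority prediction.
#'
#' @param train A [labeled_points()] with one-dimensional features.
#' @return A model list with `threshold`, `polarity` (`+1`: values at or
#'   above the threshold are assigned the second factor level; `-1`: the
#'   first) and `levels`; or a degenerate majority model.
#' @export
train_xroc <- function(train) {
  stopifnot(inherits(train, "labeled_points"))
  if (ncol(train$features) != 1)
    stop("train_xroc: XROC is defined for scalar features only",
         call. = FALSE)
  x <- train$features[, 1]
  y <- train$labels
  u <- sort(unique(x))
  if (length(u) < 2) return(fit_majority(y))
  cand <- (u[-length(u)] + u[-1]) / 2
  lv <- levels(y)
  best <- NULL
  for (thr in cand) {
    for (pol in c(1, -1)) {
      pred <- if (pol == 1) ifelse(x >= thr, lv[2], lv[1])
              else ifelse(x >= thr, lv[1], lv[2])
      acc <- mean(pred == as.character(y))
      margin <- min(abs(x - thr))
      if (is.null(best) || acc > best$acc + 1e-12 ||
          (abs(acc - best$acc) <= 1e-12 &&
           (margin > best$margin + 1e-12 ||
            (abs(margin - best$margin) <= 1e-12 && thr < best$threshold)))) {
        best <- list(threshold = thr, polarity = pol, acc = acc,
                     margin = margin)
      }
    }
  }
  structure(list(threshold = best$threshold, polarity = best$polarity,
                 levels = lv, train_accuracy = 100 * best$acc),
            class = "filmsense_xroc")
}

#' Predict with a trained ROC-threshold classifier
#'
#' @param model A model from [train_xroc()] (non-degenerate).
#' @param newdata Numeric matrix with one column (or vector) of feature
#'   values.
#' @return Factor of predicted labels.
#' @export
predict_xroc <- function(model, newdata) {
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1)
  lv <- model$levels
  x <- newdata[, 1]
  pred <- if (model$polarity == 1) ifelse(x >= model$threshold, lv[2], lv[1])
          else ifelse(x >= model$threshold, lv[1], lv[2])
  factor(pred, levels = lv)
}

# Stable column names so formula interfaces see the same frame at fit
# and predict time.
as_feature_df <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df
}

fit_one <- function(spec, x, y) {
  hp <- spec$hyperparameters
  fam <- spec$family
  df <- cbind(y = y, as_feature_df(x))
  fallback <- function(e) fit_majority(y)
  tryCatch(switch(fam,
    fine_tree = ,
    medium_tree = structure(list(
      fit = rpart::rpart(y ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                           minsplit = 2, minbucket = 1, cp = 0,
                           maxdepth = 30, xval = 0, maxcompete = 0,
                           maxsurrogate = 0))),
      class = "filmsense_rpart"),
    svm_linear = ,
    svm_quadratic = ,
    svm_cubic = structure(list(
      fit = e1071::svm(x, y,
                       kernel = if (hp$degree == 1) "linear" else
                         "polynomial",
                       degree = hp$degree, gamma = 1, coef0 = 1,
                       cost = hp$cost, scale = FALSE)),
      class = "filmsense_svm"),
    knn_cosine = ,
    knn_cubic = structure(list(x = x, y = y, k = hp$k,
                               distance = hp$distance),
                          class = "filmsense_knn"),
    lda = structure(list(fit = MASS::lda(x, grouping = y)),
                    class = "filmsense_da"),
    qda = structure(list(fit = MASS::qda(x, grouping = y)),
                    class = "filmsense_da"),
    logistic = structure(list(
      fit = suppressWarnings(stats::glm(y ~ ., data = df,
                                        family = stats::binomial())),
      levels = levels(y)),
      class = "filmsense_glm"),
    xroc = train_xroc(labeled_points(x, y))),
    error = fallback)
}

predict_one <- function(model, newdata) {
  if (inherits(model, "filmsense_majority"))
    return(predict_majority(model, newdata))
  if (inherits(model, "filmsense_rpart")) {
    return(stats::predict(model$fit, as_feature_df(newdata),
                          type = "class"))
  }
  if (inherits(model, "filmsense_svm"))
    return(stats::predict(model$fit, newdata))
  if (inherits(model, "filmsense_knn"))
    return(predict_knn(model, newdata))
  if (inherits(model, "filmsense_da")) {
    # class from the posterior argmax: MASS's own predict() breaks
    # near-ties (within ~1e-5 relative) randomly via max.col, which
    # would make LOOCV nondeterministic near the decision boundary
    post <- stats::predict(model$fit, newdata)$posterior
    lev <- colnames(post)
    return(factor(lev[apply(post, 1, which.max)], levels = lev))
  }
  if (inherits(model, "filmsense_glm")) {
    p <- suppressWarnings(stats::predict(model$fit, as_feature_df(newdata),
                                         type = "response"))
    return(factor(ifelse(p > 0.5, model$levels[2], model$levels[1]),
                  levels = model$levels))
  }
  if (inherits(model, "filmsense_xroc"))
    return(predict_xroc(model, newdata))
  stop("predict_one: unknown model class", call. = FALSE)
}

#' Leave-one-out cross-validation of one classifier
#'
#' For each point, the classifier is trained on the remaining `n - 1`
#' points and predicts the held-out point; accuracy is the percentage of
#' correct folds. If removing a point leaves a training fold with a single
#' class, that fold predicts the sole training class. The procedure is
#' fully deterministic given the data and the specification.
#'
#' @param data A [labeled_points()].
#' @param spec A [classifier_spec()].
#' @return A list of class `loocv_result`: `accuracy` (percent),
#'   `per_fold_predictions` (factor), `truth`, `classifier`.
#' @examples
#' set.seed(1)
#' pts <- labeled_points(c(rnorm(10, -1, .1), rnorm(10, 1, .1)),
#'                       rep(c("placebo", "caffeine"), each = 10))
#' loocv(pts, classifier_spec("xroc"))$accuracy
#' @export
loocv <- function(data, spec) {
  stopifnot(inherits(data, "labeled_points"),
            inherits(spec, "classifier_spec"))
  n <- nrow(data$features)
  preds <- character(n)
  for (i in seq_len(n)) {
    xtr <- data$features[-i, , drop = FALSE]
    ytr <- droplevels(data$labels[-i])
    xte <- data$features[i, , drop = FALSE]
    model <- if (nlevels(ytr) < 2) {
      fit_majority(factor(ytr, levels = levels(data$labels)))
    } else {
      fit_one(spec, xtr, factor(ytr, levels = levels(data$labels)))
    }
    preds[i] <- as.character(predict_one(model, xte))
  }
  preds <- factor(preds, levels = levels(data$labels))
  structure(list(accuracy = 100 * sum(preds == data$labels) / n,
                 per_fold_predictions = preds, truth = data$labels,
                 classifier = spec),
            class = "loocv_result")
}

#' Run the full classifier bank over all modalities
#'
#' Computes the leave-one-out accuracy of every bank classifier for each
#' modality's labelled points and lays the results out as the study's
#' accuracy table: one row per classifier (fixed order), one accuracy
#' column per modality.
#'
#' @param data_per_modality Named list mapping modality (e.g. `"ECG"`,
#'   `"EDA"`, `"RF"`) to a [labeled_points()].
#' @param bank Classifier bank; default [classifier_bank()].
#' @return A `data.frame` with columns `classifier`, `optimal_parameters`,
#'   and `acc_<modality>` (percent) per modality.
#' @export
run_classifier_bank <- function(data_per_modality,
                                bank = classifier_bank()) {
  if (is.null(names(data_per_modality)) ||
      any(!nzchar(names(data_per_modality))))
    stop("run_classifier_bank: data_per_modality must be a named list",
         call. = FALSE)
  res <- data.frame(
    classifier = vapply(bank, `[[`, character(1), "name"),
    optimal_parameters = vapply(bank, `[[`, character(1),
                                "optimal_parameters"),
    stringsAsFactors = FALSE, row.names = NULL)
  for (mod in names(data_per_modality)) {
    res[[paste0("acc_", tolower(mod))]] <-
      vapply(bank, function(entry)
        loocv(data_per_modality[[mod]], entry$spec)$accuracy, numeric(1))
  }
  res
}
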