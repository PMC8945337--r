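# Independent brute-force leave-one-out oracle. The fold loop, the
# degenerate-fold policy and the hand-rolled learners (KNN, threshold
# classifier) are re-implemented from scratch here; the library-backed
# learners call their libraries directly. Kept deliberately plain and
# structured differently from the package code path.

oracle_predict <- function(family, xtr, ytr, xte) {
  lv <- levels(ytr)
  if (length(unique(as.character(ytr))) < 2) {
    return(as.character(ytr[1]))
  }
  if (family %in% c("fine_tree", "medium_tree")) {
    df <- data.frame(y = ytr, f = xtr[, 1])
    fit <- rpart::rpart(y ~ f, data = df, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0,
                          maxdepth = 30, xval = 0, maxcompete = 0,
                          maxsurrogate = 0))
    return(as.character(predict(fit, data.frame(f = xte[, 1]),
                                type = "class")))
  }
  if (family %in% c("svm_linear", "svm_quadratic", "svm_cubic")) {
    deg <- c(svm_linear = 1, svm_quadratic = 2, svm_cubic = 3)[[family]]
    cst <- c(svm_linear = 5, svm_quadratic = 3, svm_cubic = 2)[[family]]
    fit <- e1071::svm(xtr, ytr,
                      kernel = if (deg == 1) "linear" else "polynomial",
                      degree = deg, gamma = 1, coef0 = 1, cost = cst,
                      scale = FALSE)
    return(as.character(predict(fit, xte)))
  }
  if (family %in% c("knn_cosine", "knn_cubic")) {
    d <- numeric(nrow(xtr))
    for (j in seq_len(nrow(xtr))) {
      u <- xtr[j, 1]
      v <- xte[1, 1]
      d[j] <- if (family == "knn_cubic") abs(u - v) else {
        if (u == 0 || v == 0) 1 else 1 - sign(u) * sign(v)
      }
    }
    kd <- sort(d)[min(3, length(d))]
    voters <- which(d <= kd)
    counts <- sapply(lv, function(l) sum(ytr[voters] == l))
    if (counts[1] != counts[2]) {
      return(lv[which.max(counts)])
    }
    sums <- sapply(lv, function(l) sum(d[voters][ytr[voters] == l]))
    return(lv[order(sums, seq_along(lv))[1]])
  }
  if (family == "lda") {
    fit <- MASS::lda(xtr, grouping = ytr)
    post <- predict(fit, xte)$posterior
    return(colnames(post)[which.max(post[1, ])])
  }
  if (family == "qda") {
    fit <- tryCatch(MASS::qda(xtr, grouping = ytr), error = function(e) NULL)
    if (is.null(fit)) {
      tab <- sapply(lv, function(l) sum(ytr == l))
      return(lv[which.max(tab)])
    }
    post <- predict(fit, xte)$posterior
    return(colnames(post)[which.max(post[1, ])])
  }
  if (family == "logistic") {
    df <- data.frame(y = ytr, f = xtr[, 1])
    fit <- suppressWarnings(glm(y ~ f, data = df, family = binomial()))
    p <- suppressWarnings(predict(fit, data.frame(f = xte[, 1]),
                                  type = "response"))
    return(if (p > 0.5) lv[2] else lv[1])
  }
  if (family == "xroc") {
    x <- xtr[, 1]
    u <- sort(unique(x))
    if (length(u) < 2) {
      tab <- sapply(lv, function(l) sum(ytr == l))
      return(lv[which.max(tab)])
    }
    mids <- (u[-1] + u[-length(u)]) / 2
    grid <- expand.grid(thr = mids, pol = c(1, -1))
    grid$acc <- mapply(function(thr, pol) {
      hi <- if (pol == 1) lv[2] else lv[1]
      lo <- setdiff(lv, hi)
      mean(ifelse(x >= thr, hi, lo) == as.character(ytr))
    }, grid$thr, grid$pol)
    grid$margin <- sapply(grid$thr, function(thr) min(abs(x - thr)))
    grid <- grid[order(-grid$acc, -grid$margin, grid$thr), ]
    thr <- grid$thr[1]
    pol <- grid$pol[1]
    hi <- if (pol == 1) lv[2] else lv[1]
    lo <- setdiff(lv, hi)
    return(if (xte[1, 1] >= thr) hi else lo)
  }
  stop("oracle_predict: unknown family ", family)
}

oracle_loocv_accuracy <- function(features, labels, family) {
  features <- matrix(features, ncol = 1)
  labels <- factor(labels)
  hits <- 0
  for (i in seq_len(nrow(features))) {
    pred <- oracle_predict(family,
                           features[-i, , drop = FALSE], labels[-i],
                           features[i, , drop = FALSE])
    hits <- hits + (pred == as.character(labels[i]))
  }
  100 * hits / nrow(features)
}
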