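#' AdaBoost (SAMME) with decision-tree weak learners
#'
#' Discrete AdaBoost combining depth-limited CART trees (fitted with
#' \pkg{rpart} under case weights) into a strong classifier. The
#' predicted probability of the positive class is the alpha-weighted
#' vote fraction of the ensemble, which lies in `[0, 1]`. Fitting is
#' deterministic for fixed input (the boosting loop draws no random
#' numbers).
#'
#' @param fs a [StasFeatureSet] with both classes present (alternatively
#'   a cases-by-features matrix plus `labels`).
#' @param labels optional label vector when `fs` is a bare matrix.
#' @param nEstimators maximum number of boosting rounds (default 50).
#' @param maxDepth depth of each weak-learner tree (default 1: stumps).
#' @return An object of class `adaboostModel`: weak learners, their
#'   weights (`alphas`), accumulated feature importance, and metadata.
#' @export
fitAdaboost <- function(fs, labels = NULL, nEstimators = 50L, maxDepth = 1L) {
  if (is(fs, "StasFeatureSet")) {
    x <- featureMatrix(fs)
    labels <- caseLabels(fs)
  } else x <- fs
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class")
  n <- nrow(x)
  df <- as.data.frame(x)
  colnames(df) <- paste0("F", seq_len(ncol(x))) # syntactic safety
  y <- factor(labels, levels = c("negative", "positive"))
  w <- rep(1 / n, n)
  ctl <- rpart::rpart.control(maxdepth = maxDepth, cp = -1, minsplit = 2,
                              minbucket = 1, xval = 0, maxcompete = 0,
                              maxsurrogate = 0, usesurrogate = 0)
  trees <- list()
  alphas <- numeric(0)
  importance <- setNames(numeric(ncol(x)), colnames(df))
  dat <- cbind(df, .y = y)
  for (m in seq_len(nEstimators)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctl)
    pred <- predict(fit, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 0.5) {
      if (length(trees) == 0L) { # no better-than-chance split exists
        trees[[1]] <- fit
        alphas <- 1e-10
      }
      break
    }
    alpha <- log((1 - max(err, 1e-10)) / max(err, 1e-10))
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    vi <- fit$variable.importance
    if (!is.null(vi))
      importance[names(vi)] <- importance[names(vi)] + alpha * vi
    if (err <= 0) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas,
                 featureNames = colnames(x),
                 importance = setNames(as.numeric(importance), colnames(x)),
                 nEstimators = nEstimators, maxDepth = maxDepth),
            class = "adaboostModel")
}

#' @rdname fitAdaboost
#' @param object a fitted `adaboostModel`.
#' @param newdata cases-by-features matrix or [StasFeatureSet] with (at
#'   least) the training features.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   hard labels at 0.5.
#' @param ... unused.
#' @export
predict.adaboostModel <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  x <- if (is(newdata, "StasFeatureSet")) featureMatrix(newdata) else newdata
  x <- x[, object$featureNames, drop = FALSE]
  df <- as.data.frame(x)
  colnames(df) <- paste0("F", seq_len(ncol(x)))
  votes <- numeric(nrow(x))
  for (m in seq_along(object$trees)) {
    cl <- predict(object$trees[[m]], newdata = df, type = "class")
    votes <- votes + object$alphas[m] * (cl == "positive")
  }
  p <- votes / sum(object$alphas)
  if (type == "prob") p else
    ifelse(p >= 0.5, "positive", "negative")
}

#' @export
print.adaboostModel <- function(x, ...) {
  cat(sprintf("adaboostModel: %d trees (depth <= %d) over %d features\n",
              length(x$trees), x$maxDepth, length(x$featureNames)))
  invisible(x)
}

#' Recursive feature elimination under AdaBoost
#'
#' Repeatedly fits the boosted ensemble, ranks features by their
#' accumulated (alpha-weighted) split-improvement importance, and drops
#' the lowest-ranked fraction until `nSelected` features remain. Ties
#' and never-used features rank by name order, so the procedure is
#' deterministic.
#'
#' @inheritParams fitAdaboost
#' @param nSelected target number of features (`> 0`).
#' @param stepFrac fraction of current features dropped per iteration.
#' @return Character vector of selected feature names, strongest first.
#' @export
rfeSelect <- function(fs, labels = NULL, nSelected = 20L, nEstimators = 50L,
                      maxDepth = 1L, stepFrac = 0.5) {
  if (is(fs, "StasFeatureSet")) {
    x <- featureMatrix(fs)
    labels <- caseLabels(fs)
  } else x <- fs
  if (nSelected <= 0) stop("nSelected must be positive")
  if (nSelected > ncol(x))
    stop("nSelected exceeds the number of available features")
  current <- colnames(x)
  repeat {
    fit <- fitAdaboost(x[, current, drop = FALSE], labels,
                       nEstimators = nEstimators, maxDepth = maxDepth)
    imp <- fit$importance
    ranked <- names(imp)[order(-imp, names(imp))]
    if (length(current) == nSelected) return(ranked)
    nKeep <- max(nSelected, floor(length(current) * (1 - stepFrac)))
    if (nKeep >= length(current)) nKeep <- length(current) - 1L
    current <- ranked[seq_len(nKeep)]
  }
}
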