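# Preprocessing: stratified splitting, training-anchored z-scoring,
# Pearson-correlation deduplication, SMOTE. Every "fit" here happens on
# training cases only; held-out tables are transformed with the training
# parameters, never refitted.

#' Stratified train/test split
#'
#' Splits by class with `floor(n_class * trainFrac)` training cases per
#' class, so class proportions are preserved to rounding and the split
#' is disjoint and exhaustive. Deterministic given the seed.
#'
#' @param fs a [StasFeatureSet].
#' @param trainFrac training fraction in (0, 1].
#' @param seed integer seed.
#' @return list with `train` and `test` [StasFeatureSet]s and the index
#'   vectors `trainIdx` / `testIdx`.
#' @export
stratifiedSplit <- function(fs, trainFrac = 0.8, seed = 1L) {
  stopifnot(is(fs, "StasFeatureSet"), trainFrac > 0, trainFrac <= 1)
  lab <- caseLabels(fs)
  if (length(unique(lab)) < 2L)
    stop("both classes must be present to split")
  if (any(table(lab) < 2L)) stop("each class needs at least 2 cases")
  trainIdx <- withSeed(seed, {
    unlist(lapply(unique(lab), function(cl) {
      idx <- which(lab == cl)
      sample(idx, floor(length(idx) * trainFrac))
    }))
  })
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(lab), trainIdx)
  list(train = subsetCases(fs, trainIdx),
       test = if (length(testIdx)) subsetCases(fs, testIdx) else NULL,
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Z-score standardisation fitted on training data
#'
#' Fits per-feature mean and SD on the training table, drops
#' zero-variance features (logged in the result), and transforms the
#' training table and any number of held-out tables with the training
#' parameters.
#'
#' @param train a [StasFeatureSet].
#' @param ... further [StasFeatureSet]s to transform with the training
#'   parameters.
#' @return list with `train`, `others` (list), and `dropped` (names of
#'   zero-variance features). Transformed sets carry the fitted
#'   parameters in `metadata(x)$zscore`.
#' @export
zscoreFitApply <- function(train, ...) {
  stopifnot(is(train, "StasFeatureSet"))
  m <- featureMatrix(train)
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  keep <- !is.na(sdev) & sdev > 0
  dropped <- colnames(m)[!keep]
  transform <- function(fs) {
    x <- featureMatrix(fs)[, keep, drop = FALSE]
    x <- sweep(sweep(x, 2, mu[keep]), 2, sdev[keep], "/")
    out <- stasFeatureSet(x, caseLabels(fs))
    metadata(out)$zscore <- list(mean = mu[keep], sd = sdev[keep])
    out
  }
  others <- lapply(list(...), transform)
  list(train = transform(train), others = others, dropped = dropped)
}

#' Pearson-correlation deduplication
#'
#' Removes one member of every feature pair whose absolute Pearson
#' correlation exceeds the threshold (default 0.99). Features are
#' scanned in name order and the later member of an offending pair is
#' removed, so the result is deterministic. Pairs with zero variance
#' have an undefined coefficient and are never removed here (the z-score
#' step drops them beforehand).
#'
#' @param fs a [StasFeatureSet] (standardised).
#' @param threshold correlation magnitude above which one feature of a
#'   pair is dropped.
#' @return The reduced [StasFeatureSet] with attribute
#'   `metadata(x)$pccRemoved` listing removed features.
#' @export
pccFilter <- function(fs, threshold = 0.99) {
  stopifnot(is(fs, "StasFeatureSet"))
  m <- featureMatrix(fs)
  ord <- order(colnames(m))
  m <- m[, ord, drop = FALSE]
  cc <- suppressWarnings(cor(m))
  cc[is.na(cc)] <- 0
  p <- ncol(m)
  keep <- rep(TRUE, p)
  for (a in seq_len(p - 1)) {
    if (!keep[a]) next
    bad <- which(abs(cc[a, ]) > threshold)
    bad <- bad[bad > a]
    keep[bad] <- FALSE
  }
  kept <- colnames(m)[keep]
  out <- setFeatureMatrix(fs, featureMatrix(fs)[, kept, drop = FALSE])
  metadata(out)$pccRemoved <- colnames(m)[!keep]
  out
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority cases are interpolations `x + u * (x_nn - x)` with
#' `u ~ U(0, 1)` between a minority case and one of its `k` nearest
#' minority neighbours (Euclidean distance in feature space). Only ever
#' applied to training data; inside cross-validation it runs inside each
#' training fold. Already-balanced input is returned unchanged.
#'
#' @param fs a [StasFeatureSet] (training cases only).
#' @param k number of nearest neighbours (reduced with a warning when
#'   the minority class is smaller than `k + 1`).
#' @param seed integer seed.
#' @return A balanced [StasFeatureSet]; synthetic cases are named
#'   `smote001`, ...
#' @export
smoteOversample <- function(fs, k = 5L, seed = 1L) {
  stopifnot(is(fs, "StasFeatureSet"))
  lab <- caseLabels(fs)
  tab <- table(factor(lab, levels = c("negative", "positive")))
  if (any(tab == 0)) stop("both classes must be present")
  minority <- names(tab)[which.min(tab)]
  nNew <- abs(tab[[1]] - tab[[2]])
  if (nNew == 0) return(fs)
  minIdx <- which(lab == minority)
  if (length(minIdx) < 2L)
    stop("SMOTE needs at least 2 minority cases")
  if (length(minIdx) < k + 1L) {
    k <- length(minIdx) - 1L
    warning(sprintf("minority class smaller than k+1; k reduced to %d", k))
  }
  m <- featureMatrix(fs)
  xm <- m[minIdx, , drop = FALSE]
  dd <- as.matrix(dist(xm))
  diag(dd) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(dd)),
                              function(i) order(dd[i, ])[seq_len(k)]))
  synth <- withSeed(seed, {
    base <- rep(seq_along(minIdx), length.out = nNew)
    rows <- lapply(base, function(b) {
      j <- nn[b, sample.int(k, 1)]
      u <- runif(1)
      xm[b, ] + u * (xm[j, ] - xm[b, ])
    })
    do.call(rbind, rows)
  })
  rownames(synth) <- sprintf("smote%03d", seq_len(nNew))
  out <- stasFeatureSet(rbind(m, synth),
                        c(lab, rep(minority, nNew)))
  metadata(out) <- metadata(fs)
  out
}
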