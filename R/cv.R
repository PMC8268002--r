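#' Model configuration
#'
#' Bundles the knobs of one modeling run: which VOI(s), which feature
#' group, how many features RFE keeps, fold/iteration counts and the
#' AdaBoost settings. The hyperparameter grid defaults to
#' {50, 100, 200} estimators x tree depth {1, 2, 3}.
#'
#' @param voiScope `"eightVoi"` or one VOI id
#'   (`"core"`, `"s2"`, `"s4"`, `"s6"`, `"s8"`, `"s10"`, `"s20"`, `"band"`).
#' @param featureGroup one of `"all"`, `"firstorder_shape"`, `"texture"`,
#'   `"wavelet"`, `"firstorder"`.
#' @param nSelected RFE target feature count (default 20).
#' @param cvFolds stratified folds (default 5).
#' @param iterations repeats of the cross-validation over which per-case
#'   probabilities are averaged (default 5).
#' @param nEstimators,maxDepth AdaBoost settings used when no grid
#'   search is run.
#' @param smoteK SMOTE neighbour count.
#' @param seed master seed of the run.
#' @return A `modelSpec` list.
#' @export
modelSpec <- function(voiScope = "eightVoi", featureGroup = "all",
                      nSelected = 20L, cvFolds = 5L, iterations = 5L,
                      nEstimators = 50L, maxDepth = 1L, smoteK = 5L,
                      seed = 1L) {
  stopifnot(cvFolds >= 2L, iterations >= 1L)
  voiScope <- match.arg(voiScope, c("eightVoi", "core", "s2", "s4", "s6",
                                    "s8", "s10", "s20", "band"))
  featureGroup <- match.arg(featureGroup,
                            c("all", "firstorder_shape", "texture",
                              "wavelet", "firstorder"))
  structure(list(voiScope = voiScope, featureGroup = featureGroup,
                 nSelected = as.integer(nSelected),
                 cvFolds = as.integer(cvFolds),
                 iterations = as.integer(iterations),
                 nEstimators = as.integer(nEstimators),
                 maxDepth = as.integer(maxDepth),
                 smoteK = as.integer(smoteK), seed = as.integer(seed)),
            class = "modelSpec")
}

# column filter implementing voiScope x featureGroup on case-level
# feature names of the form "<voi>__<filter>_<family>_<feature>"
scopeColumns <- function(featNames, voiScope, featureGroup) {
  keep <- rep(TRUE, length(featNames))
  if (voiScope != "eightVoi")
    keep <- startsWith(featNames, paste0(voiScope, "__"))
  pat <- switch(featureGroup,
    all = NULL,
    firstorder_shape = "__shape_|__original_firstorder_",
    texture = "__original_(glcm|glrlm|glszm|gldm)_",
    wavelet = "__wavelet\\.",
    firstorder = "__original_firstorder_")
  if (!is.null(pat)) keep <- keep & grepl(pat, featNames)
  featNames[keep]
}

# stratified fold assignment; guarantees both classes in every fold when
# each class has >= cvFolds cases
makeFolds <- function(labels, k, seed) {
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

# the per-fold training pipeline: zscore -> PCC filter -> SMOTE -> RFE ->
# AdaBoost. Returns the fitted model plus everything needed to transform
# held-out cases identically.
fitFoldPipeline <- function(train, spec, seed) {
  zs <- zscoreFitApply(train)
  ztrain <- pccFilter(zs$train, 0.99)
  btrain <- smoteOversample(ztrain, k = spec$smoteK, seed = seed)
  nSel <- min(spec$nSelected, ncol(featureMatrix(btrain)))
  sel <- rfeSelect(setFeatureMatrix(btrain, featureMatrix(btrain)),
                   nSelected = nSel, nEstimators = spec$nEstimators,
                   maxDepth = spec$maxDepth)
  model <- fitAdaboost(featureMatrix(btrain)[, sel, drop = FALSE],
                       caseLabels(btrain),
                       nEstimators = spec$nEstimators,
                       maxDepth = spec$maxDepth)
  list(model = model, zscore = metadata(zs$train)$zscore, selected = sel)
}

# transform held-out cases with a fitted fold pipeline and predict
predictFoldPipeline <- function(fit, fs) {
  x <- featureMatrix(fs)
  zc <- fit$zscore
  x <- sweep(sweep(x[, names(zc$mean), drop = FALSE], 2, zc$mean), 2,
             zc$sd, "/")
  predict(fit$model, x[, fit$selected, drop = FALSE])
}

#' Out-of-fold cross-validated probabilities
#'
#' Runs `iterations` repeats of stratified `cvFolds`-fold
#' cross-validation. Inside every training fold the full preprocessing
#' chain (z-score, correlation filter, SMOTE, RFE, AdaBoost) is refitted
#' from scratch, so no information leaks into the held-out fold. Every
#' case receives one out-of-fold probability per iteration; the average
#' over iterations is the reported probability.
#'
#' @param fs a [StasFeatureSet].
#' @param spec a [modelSpec()] (its `voiScope`/`featureGroup` select
#'   columns of `fs`).
#' @return list with `prob` (averaged out-of-fold probability per case),
#'   `folds` (cases x iterations fold assignment), `auc` (AUC of `prob`
#'   against the labels), and `labels`.
#' @export
crossValidatedProbabilities <- function(fs, spec = modelSpec()) {
  stopifnot(is(fs, "StasFeatureSet"))
  cols <- scopeColumns(rownames(fs), spec$voiScope, spec$featureGroup)
  if (!length(cols)) stop("no features match the requested scope/group")
  fsub <- setFeatureMatrix(fs, featureMatrix(fs)[, cols, drop = FALSE])
  lab <- caseLabels(fsub)
  n <- length(lab)
  probs <- matrix(NA_real_, n, spec$iterations)
  folds <- matrix(NA_integer_, n, spec$iterations)
  for (it in seq_len(spec$iterations)) {
    fseed <- deriveSeed(spec$seed, it)
    fold <- makeFolds(lab, spec$cvFolds, fseed)
    for (attempt in 1:10) {  # refold if a fold lost a class
      bad <- vapply(seq_len(spec$cvFolds), function(f)
        length(unique(lab[fold != f])) < 2L, TRUE)
      if (!any(bad)) break
      message("refolding: a training fold lost a class")
      fseed <- deriveSeed(fseed, 97L)
      fold <- makeFolds(lab, spec$cvFolds, fseed)
    }
    for (f in seq_len(spec$cvFolds)) {
      trIdx <- which(fold != f)
      teIdx <- which(fold == f)
      if (!length(teIdx)) next
      fit <- fitFoldPipeline(subsetCases(fsub, trIdx), spec,
                             seed = deriveSeed(fseed, f))
      probs[teIdx, it] <- predictFoldPipeline(fit, subsetCases(fsub, teIdx))
    }
    folds[, it] <- fold
  }
  prob <- rowMeans(probs)
  list(prob = prob, folds = folds, labels = lab,
       auc = rocCurveAuc(prob, lab)$auc)
}

#' Grid search over AdaBoost hyperparameters
#'
#' Evaluates every grid point by the mean validation-fold AUC of a
#' cross-validation run and returns the winner. Ties break toward fewer
#' estimators, then shallower trees (the selection criterion is the
#' validation AUC, not accuracy).
#'
#' @param fs a [StasFeatureSet].
#' @param spec a [modelSpec()].
#' @param grid data frame with columns `nEstimators` and `maxDepth`.
#' @return list with `best` (one-row data frame) and `results` (grid
#'   with an `auc` column).
#' @export
gridSearch <- function(fs, spec = modelSpec(),
                       grid = expand.grid(nEstimators = c(50L, 100L, 200L),
                                          maxDepth = 1:3)) {
  stopifnot(nrow(grid) >= 1L)
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    sp <- spec
    sp$nEstimators <- grid$nEstimators[g]
    sp$maxDepth <- grid$maxDepth[g]
    sp$iterations <- 1L
    cv <- crossValidatedProbabilities(fs, sp)
    # mean per-fold validation AUC
    fold <- cv$folds[, 1]
    mean(vapply(unique(fold), function(f) {
      idx <- fold == f
      if (length(unique(cv$labels[idx])) < 2L) return(NA_real_)
      rocCurveAuc(cv$prob[idx], cv$labels[idx])$auc
    }, 0), na.rm = TRUE)
  }, 0)
  ord <- order(-aucs, grid$nEstimators, grid$maxDepth)
  res <- cbind(grid, auc = aucs)
  list(best = res[ord[1], , drop = FALSE], results = res)
}

#' Fit and evaluate the nine radiomic models
#'
#' Fits the eight single-VOI models (core, six shells, interface band)
#' and the combined eight-VOI model for the requested feature group.
#' Each model is trained on a stratified 80% split with out-of-fold
#' cross-validated probabilities providing the training AUC, then
#' refitted on the whole training split and applied to the held-out 20%
#' for the test AUC.
#'
#' @param fs a case-level [StasFeatureSet] (VOI-prefixed feature names).
#' @param featureGroup feature group for every model (see [modelSpec()]).
#' @param trainFrac training fraction of the stratified split.
#' @param spec template [modelSpec()]; its `voiScope` is overridden per
#'   model.
#' @param seed master seed (split + CV).
#' @return data frame with one row per model: `model`, `aucTrain`,
#'   `aucTest`.
#' @export
runNineModels <- function(fs, featureGroup = "all", trainFrac = 0.8,
                          spec = modelSpec(), seed = 1L) {
  models <- c("s2", "s4", "s6", "s8", "s10", "s20", "band", "core",
              "eightVoi")
  sp <- stratifiedSplit(fs, trainFrac, seed = seed)
  rows <- lapply(models, function(mo) {
    msp <- spec
    msp$voiScope <- mo
    msp$featureGroup <- featureGroup
    msp$seed <- deriveSeed(seed, match(mo, models))
    cv <- crossValidatedProbabilities(sp$train, msp)
    cols <- scopeColumns(rownames(fs), mo, featureGroup)
    trainSub <- setFeatureMatrix(sp$train,
                                 featureMatrix(sp$train)[, cols, drop = FALSE])
    fit <- fitFoldPipeline(trainSub, msp, seed = deriveSeed(msp$seed, 0L))
    aucTest <- if (!is.null(sp$test)) {
      testSub <- setFeatureMatrix(sp$test,
                                  featureMatrix(sp$test)[, cols, drop = FALSE])
      rocCurveAuc(predictFoldPipeline(fit, testSub),
                  caseLabels(testSub))$auc
    } else NA_real_
    data.frame(model = mo, aucTrain = cv$auc, aucTest = aucTest)
  })
  do.call(rbind, rows)
}
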