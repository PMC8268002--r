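cvToy <- function(n = 60, p = 12, nPos = 24, seed = 1, effect = 0,
                  prefix = "core") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- sprintf("%s__original_firstorder_F%02d", prefix, 1:p)
    rownames(m) <- sprintf("c%03d", 1:n)
    lab <- rep(c("positive", "negative"), c(nPos, n - nPos))
    m[lab == "positive", 1:2] <- m[lab == "positive", 1:2] + effect
    stasFeatureSet(m, lab)
  })
}

test_that("out-of-fold probabilities cover every case and stay in [0,1]", {
  fs <- cvToy(effect = 1.5)
  spec <- modelSpec(voiScope = "core", featureGroup = "firstorder",
                    nSelected = 5L, iterations = 2L, seed = 3)
  expect_equal(spec$cvFolds, 5L) # five folds by default
  cv <- crossValidatedProbabilities(fs, spec)
  expect_length(cv$prob, 60)
  expect_false(any(is.na(cv$prob)))
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  # every case is assigned exactly one fold per iteration
  expect_equal(dim(cv$folds), c(60L, 2L))
  expect_true(all(cv$folds %in% 1:5))
  # informative features push the out-of-fold AUC well above chance
  expect_gt(cv$auc, 0.8)
  # bit-reproducible under the same spec
  cv2 <- crossValidatedProbabilities(fs, spec)
  expect_identical(cv$prob, cv2$prob)
})

test_that("pure-noise features give chance-level out-of-fold AUC (no leakage)", {
  aucs <- vapply(1:20, function(s) {
    fs <- cvToy(n = 40, p = 8, nPos = 16, seed = 100 + s, effect = 0)
    crossValidatedProbabilities(
      fs, modelSpec(voiScope = "core", featureGroup = "firstorder",
                    nSelected = 4L, iterations = 1L, seed = s))$auc
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("grid search picks the dominant configuration", {
  # XOR-style labels: stumps cannot express the interaction, depth-2 can
  fs <- withr::with_seed(5, {
    n <- 80
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    lab <- ifelse(xor(x1 > 0, x2 > 0), "positive", "negative")
    m <- cbind(x1, x2, matrix(rnorm(n * 2), n))
    colnames(m) <- sprintf("core__original_firstorder_F%02d", 1:4)
    rownames(m) <- sprintf("c%03d", 1:n)
    stasFeatureSet(m, lab)
  })
  spec <- modelSpec(voiScope = "core", featureGroup = "firstorder",
                    nSelected = 4L, seed = 2)
  gs <- gridSearch(fs, spec,
                   grid = data.frame(nEstimators = c(50L, 50L),
                                     maxDepth = c(1L, 2L)))
  expect_equal(gs$best$maxDepth, 2L)
  expect_equal(nrow(gs$results), 2)
  # one-point grid returns that point
  one <- gridSearch(fs, spec, grid = data.frame(nEstimators = 10L,
                                                maxDepth = 1L))
  expect_equal(one$best$nEstimators, 10L)
})

test_that("tied grid points resolve toward the simpler model", {
  # constant features: every configuration scores identically
  fs <- cvToy(n = 40, p = 3, nPos = 16, seed = 9, effect = 0)
  spec <- modelSpec(voiScope = "core", featureGroup = "firstorder",
                    nSelected = 3L, seed = 4)
  m <- featureMatrix(fs) * 0 + rep(c(0.5, -0.5), 20)
  fsc <- setFeatureMatrix(fs, m)
  gs <- gridSearch(fsc, spec,
                   grid = data.frame(nEstimators = c(100L, 50L),
                                     maxDepth = c(2L, 2L)))
  expect_equal(gs$best$nEstimators, 50L)
})

test_that("the nine-model table has the expected shape and ordering", {
  # small cohort-like table with VOI-prefixed columns
  vois <- c("core", "s2", "s4", "s6", "s8", "s10", "s20", "band")
  fs <- withr::with_seed(11, {
    n <- 60
    blocks <- lapply(vois, function(v) {
      m <- matrix(rnorm(n * 3), n, 3)
      colnames(m) <- sprintf("%s__original_firstorder_F%02d", v, 1:3)
      m
    })
    m <- do.call(cbind, blocks)
    rownames(m) <- sprintf("c%03d", 1:n)
    lab <- rep(c("positive", "negative"), c(24, 36))
    # plant signal in the shells only
    for (v in paste0(c("s2", "s10"), "__")) {
      cols <- startsWith(colnames(m), v)
      m[lab == "positive", cols] <- m[lab == "positive", cols] + 2
    }
    stasFeatureSet(m, lab)
  })
  res <- runNineModels(fs, featureGroup = "firstorder",
                       spec = modelSpec(nSelected = 3L, iterations = 1L),
                       seed = 5)
  expect_equal(nrow(res), 9)
  expect_setequal(res$model, c(vois, "eightVoi"))
  expect_true(all(res$aucTrain >= 0 & res$aucTrain <= 1))
  expect_true(all(res$aucTest >= 0 & res$aucTest <= 1))
  # shell-only signal: the combined model beats the core model
  expect_gt(res$aucTrain[res$model == "eightVoi"],
            res$aucTrain[res$model == "core"])
})
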