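test_that("contingency metrics handle chance and undefined rates", {
  even <- metricsFromCounts(5, 5, 5, 5)
  expect_equal(even$auc, 0.5)
  expect_equal(even$accuracy, 0.5)
  # zero denominators surface as NA, never silently as 0
  noPos <- metricsFromCounts(0, 0, 3, 7)
  expect_true(is.na(noPos$sensitivity))
  expect_true(is.na(noPos$auc))
  expect_equal(noPos$specificity, 0.7)
  noPred <- metricsFromCounts(0, 4, 0, 6)
  expect_true(is.na(noPred$ppv))
  expect_error(metricsFromCounts(-1, 0, 0, 2), "non-negative")
})

test_that("binary predictors: ROC AUC equals (sens + spec) / 2 exactly", {
  # exhaustive over all 2x2 tables with moderate totals, plus larger
  # random tables
  tables <- list()
  for (tp in 0:3) for (fn in 0:3) for (fp in 0:3) for (tn in 0:3)
    if ((tp + fn) > 0 && (fp + tn) > 0)
      tables[[length(tables) + 1]] <- c(tp, fn, fp, tn)
  tables <- c(tables, list(c(14, 42, 6, 154), c(38, 18, 52, 108),
                           c(32, 24, 63, 97)))
  for (tb in tables) {
    scores <- rep(c(1, 0, 1, 0), tb)
    labels <- rep(c("positive", "positive", "negative", "negative"), tb)
    expect_equal(rocCurveAuc(scores, labels)$auc,
                 metricsFromCounts(tb[1], tb[2], tb[3], tb[4])$auc,
                 info = paste(tb, collapse = ","))
  }
})

test_that("AUC equals exhaustive pair counting, ties included", {
  expect_equal(rocCurveAuc(c(3, 4, 1, 2),
                           c("positive", "positive", "negative",
                             "negative"))$auc, 1)
  for (seed in 1:8) {
    withr::with_seed(seed, {
      scores <- sample(seq(0, 1, 0.1), 20, replace = TRUE) # forces ties
      labels <- sample(c("positive", "negative"), 20, replace = TRUE,
                       prob = c(0.4, 0.6))
    })
    if (length(unique(labels)) < 2) next
    expect_equal(rocCurveAuc(scores, labels)$auc,
                 oracleAuc(scores, labels))
  }
  expect_error(rocCurveAuc(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(4, {
    scores <- rnorm(30)
    labels <- sample(c("positive", "negative"), 30, replace = TRUE)
  })
  a <- rocCurveAuc(scores, labels)$auc
  expect_equal(rocCurveAuc(exp(scores), labels)$auc, a)
  expect_equal(rocCurveAuc(2 * scores - 7, labels)$auc, a)
})

test_that("the Youden threshold maximizes J over an exhaustive scan", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      scores <- round(runif(25), 2)
      labels <- sample(c("positive", "negative"), 25, replace = TRUE)
    })
    if (length(unique(labels)) < 2) next
    yt <- youdenThreshold(scores, labels)
    pos <- labels == "positive"
    bestJ <- max(vapply(c(-Inf, unique(scores), Inf), function(t)
      mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1, 0))
    expect_equal(yt$youdenJ, bestJ)
    expect_equal(yt$youdenJ, yt$sensitivity + yt$specificity - 1)
  }
  # perfectly separable scores reach J = 1
  yt <- youdenThreshold(c(0.9, 0.8, 0.1, 0.2),
                        c("positive", "positive", "negative", "negative"))
  expect_equal(yt$youdenJ, 1)
})

test_that("bootstrap CI defaults, coverage of the point estimate, degeneracy", {
  withr::with_seed(5, {
    scores <- c(rnorm(30, 1), rnorm(40))
    labels <- rep(c("positive", "negative"), c(30, 40))
  })
  ci <- bootstrapCi(scores, labels, seed = 1)
  expect_equal(ci$nBoot, 1000L)
  expect_true(ci$ciLow <= ci$auc && ci$auc <= ci$ciHigh)
  inside <- vapply(1:20, function(s) {
    b <- bootstrapCi(scores, labels, nBoot = 200, seed = s)
    b$ciLow <= b$auc && b$auc <= b$ciHigh
  }, TRUE)
  expect_gte(mean(inside), 0.99)
  # constant scores: every resampled AUC is 0.5
  flat <- bootstrapCi(rep(0.3, 20), rep(c("positive", "negative"), 10),
                      nBoot = 50, seed = 2)
  expect_equal(c(flat$ciLow, flat$ciHigh), c(0.5, 0.5))
})

test_that("bootstrap intervals tighten with the sample size", {
  width <- function(n, seed) {
    withr::with_seed(seed, {
      scores <- c(rnorm(n / 2, 0.8), rnorm(n / 2))
      labels <- rep(c("positive", "negative"), each = n / 2)
    })
    ci <- bootstrapCi(scores, labels, nBoot = 300, seed = seed)
    ci$ciHigh - ci$ciLow
  }
  expect_lt(mean(vapply(1:5, function(s) width(500, s), 0)),
            mean(vapply(1:5, function(s) width(50, s), 0)))
})

test_that("DeLong: identical scores give z = 0, p = 1; pROC agrees", {
  withr::with_seed(6, {
    labels <- rep(c("positive", "negative"), c(14, 16))
    a <- rnorm(30) + (labels == "positive") * 1.2
    b <- rnorm(30) + (labels == "positive") * 0.4
  })
  same <- delongTest(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  dt <- delongTest(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, levels = c("negative", "positive"),
                                  direction = "<", quiet = TRUE),
                        pROC::roc(labels, b, levels = c("negative", "positive"),
                                  direction = "<", quiet = TRUE),
                        method = "delong")
  expect_equal(unname(dt$z), unname(ref$statistic), tolerance = 1e-9)
  expect_equal(dt$p, ref$p.value, tolerance = 1e-9)
  expect_equal(dt$aucA, as.numeric(pROC::auc(labels, a,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
  expect_error(delongTest(a, b[-1], labels), "equal length")
})

test_that("DeLong variance matches an independent placement reimplementation", {
  withr::with_seed(7, {
    labels <- rep(c("positive", "negative"), c(10, 20))
    a <- rnorm(30) + (labels == "positive")
    b <- 0.5 * a + rnorm(30)
  })
  dt <- delongTest(a, b, labels)
  # direct reimplementation from the definition
  x <- which(labels == "positive")
  y <- which(labels == "negative")
  psi <- function(u, v) (u > v) + 0.5 * (u == v)
  V10 <- function(s) vapply(x, function(i) mean(psi(s[i], s[y])), 0)
  V01 <- function(s) vapply(y, function(j) mean(psi(s[x], s[j])), 0)
  S <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  va <- V10(a); vb <- V10(b); wa <- V01(a); wb <- V01(b)
  varDiff <- (S(va, va) + S(vb, vb) - 2 * S(va, vb)) / length(x) +
             (S(wa, wa) + S(wb, wb) - 2 * S(wa, wb)) / length(y)
  zRef <- (mean(va) - mean(vb)) / sqrt(varDiff)
  expect_equal(dt$z, zRef, tolerance = 1e-9)
})

test_that("package AUC matches pROC on random scores", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      labels <- sample(c("positive", "negative"), 40, replace = TRUE)
      scores <- rnorm(40)
    })
    if (length(unique(labels)) < 2) next
    expect_equal(rocCurveAuc(scores, labels)$auc,
                 as.numeric(pROC::auc(labels, scores,
                                      levels = c("negative", "positive"),
                                      direction = "<", quiet = TRUE)))
  }
})
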