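# helper: quick synthetic feature set
makeFs <- function(n = 20, p = 6, nPos = 8, seed = 1, informative = 0,
                   effect = 2) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("c%03d", 1:n), sprintf("f%02d", 1:p)))
    lab <- rep(c("positive", "negative"), c(nPos, n - nPos))
    if (informative > 0)
      m[lab == "positive", seq_len(informative)] <-
        m[lab == "positive", seq_len(informative)] + effect
    stasFeatureSet(m, lab)
  })
}

test_that("stratified split preserves class proportions via floor rounding", {
  fs <- makeFs(n = 216, p = 3, nPos = 56)
  sp <- stratifiedSplit(fs, 0.8, seed = 3)
  expect_equal(length(sp$trainIdx), 172) # floor(56*.8) + floor(160*.8)
  expect_equal(length(sp$testIdx), 44)
  expect_equal(sum(caseLabels(sp$train) == "positive"), 44)
  expect_equal(sum(caseLabels(sp$test) == "positive"), 12)
  expect_equal(sort(c(sp$trainIdx, sp$testIdx)), 1:216) # disjoint, exhaustive
  # full-fraction split leaves no test cases
  expect_null(stratifiedSplit(fs, 1, seed = 1)$test)
  # seed-reproducible, seed-sensitive
  expect_identical(stratifiedSplit(fs, 0.8, seed = 3)$trainIdx, sp$trainIdx)
  expect_false(identical(stratifiedSplit(fs, 0.8, seed = 4)$trainIdx,
                         sp$trainIdx))
  expect_error(stratifiedSplit(makeFs(n = 5, nPos = 5), 0.8, 1), "class")
})

test_that("z-scoring anchors on the training set and drops constants", {
  fs <- makeFs(n = 12, p = 4, nPos = 5, seed = 2)
  m <- featureMatrix(fs)
  m[, 4] <- 7 # constant feature
  fs <- stasFeatureSet(m, caseLabels(fs))
  te <- makeFs(n = 6, p = 4, nPos = 3, seed = 9)
  zs <- zscoreFitApply(fs, te)
  expect_equal(zs$dropped, "f04")
  zm <- featureMatrix(zs$train)
  expect_equal(unname(colMeans(zm)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(zm, 2, sd)), rep(1, 3), tolerance = 1e-9)
  # held-out cases transformed with the training mean/sd, by hand
  mu <- colMeans(m[, 1:3])
  sdv <- apply(m[, 1:3], 2, sd)
  expect_equal(featureMatrix(zs$others[[1]]),
               sweep(sweep(featureMatrix(te)[, 1:3], 2, mu), 2, sdv, "/"))
})

test_that("PCC filter removes the later member of correlated pairs", {
  x <- c(1, 2, 3)
  m <- cbind(a = x, b = c(2, 4, 6), c = c(3, 2, 1), d = c(1.2, 0.3, 2))
  rownames(m) <- c("r1", "r2", "r3")
  fs <- stasFeatureSet(m, c("positive", "positive", "negative"))
  red <- pccFilter(fs)
  # a~b have rho = 1, a~c rho = -1: only "a" (earliest by name) survives
  expect_equal(sort(colnames(featureMatrix(red))), c("a", "d"))
  expect_equal(sort(S4Vectors::metadata(red)$pccRemoved), c("b", "c"))
  # no surviving pair exceeds the bound
  cc <- cor(featureMatrix(red))
  expect_true(all(abs(cc[upper.tri(cc)]) <= 0.99))
  # duplicated feature: exactly one copy survives
  m2 <- cbind(m[, c("a", "d")], a2 = x)
  fs2 <- stasFeatureSet(m2, c("positive", "positive", "negative"))
  expect_equal(sort(colnames(featureMatrix(pccFilter(fs2)))), c("a", "d"))
  # a permissive threshold keeps everything
  expect_equal(ncol(featureMatrix(pccFilter(fs, threshold = 1.01))), 4)
})

test_that("SMOTE balances classes by segment interpolation", {
  fs <- makeFs(n = 30, p = 4, nPos = 9, seed = 5)
  bal <- smoteOversample(fs, seed = 11)
  tab <- table(caseLabels(bal))
  expect_equal(unname(tab[["positive"]]), unname(tab[["negative"]]))
  # the paper-scale contract: 46 vs 126 -> 126 vs 126
  big <- makeFs(n = 172, p = 5, nPos = 46, seed = 6)
  balBig <- smoteOversample(big, seed = 1)
  expect_equal(as.integer(table(caseLabels(balBig))), c(126L, 126L))
  # synthetic points lie on segments between real minority points
  orig <- featureMatrix(fs)[caseLabels(fs) == "positive", ]
  synth <- featureMatrix(bal)[grepl("^smote", rownames(featureMatrix(bal))), ]
  for (r in seq_len(nrow(synth))) {
    s <- synth[r, ]
    onSegment <- vapply(seq_len(nrow(orig)), function(a) {
      any(vapply(seq_len(nrow(orig)), function(b) {
        if (a == b) return(FALSE)
        dv <- orig[b, ] - orig[a, ]
        t <- if (abs(dv[1]) > 1e-12) (s[1] - orig[a, 1]) / dv[1] else 0
        t >= -1e-9 && t <= 1 + 1e-9 &&
          all(abs(orig[a, ] + t * dv - s) < 1e-9)
      }, TRUE))
    }, TRUE)
    expect_true(any(onSegment))
  }
  # deterministic given the seed
  expect_identical(featureMatrix(smoteOversample(fs, seed = 11)),
                   featureMatrix(bal))
  # balanced input returned unchanged
  even <- makeFs(n = 10, p = 3, nPos = 5)
  expect_identical(featureMatrix(smoteOversample(even, seed = 1)),
                   featureMatrix(even))
  # k shrinks with a warning; tiny minorities error
  expect_warning(smoteOversample(makeFs(n = 12, p = 3, nPos = 3), k = 5),
                 "reduced")
  expect_error(smoteOversample(makeFs(n = 12, p = 3, nPos = 1)), "minority|class")
})
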