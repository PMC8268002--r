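test_that("GLCM counts match exhaustive pair enumeration", {
  # 2 x 2 x 1 toy with levels [1 2; 1 2]: one in-plane direction holds
  # the (1,2) pairs twice, symmetric
  g <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  tm <- textureMatrix(asDisc(g), "glcm")
  counts <- tm$data
  expect_equal(sum(counts), 12) # 6 voxel pairs, double-counted
  # the cross-level in-plane direction carries exactly {(1,2):2, (2,1):2}
  cross <- vapply(seq_len(dim(counts)[3]), function(a)
    identical(unname(counts[, , a]), matrix(c(0, 2, 2, 0), 2, 2)), TRUE)
  expect_equal(sum(cross), 1)
  for (seed in 1:10) {
    gr <- randomGrid(seed)
    tm <- textureMatrix(asDisc(gr), "glcm")
    expect_equal(unname(tm$data), unname(oracleGlcm(gr, max(gr))),
                 info = paste("seed", seed))
  }
})

test_that("GLRLM counts match exhaustive run enumeration", {
  for (seed in 1:10) {
    gr <- randomGrid(seed)
    tm <- textureMatrix(asDisc(gr), "glrlm")
    expect_equal(unname(tm$data), unname(oracleGlrlm(gr, max(gr))),
                 info = paste("seed", seed))
  }
})

test_that("GLSZM zones match flood-fill enumeration", {
  # two disconnected single voxels of level 1 -> entry (1, size 1) = 2
  g <- array(0L, c(4, 4, 1))
  g[1, 1, 1] <- 1L
  g[4, 4, 1] <- 1L
  z <- textureMatrix(asDisc(g), "glszm")$data
  expect_equal(z$count[z$level == 1 & z$size == 1], 2)
  for (seed in 1:10) {
    gr <- randomGrid(seed)
    z <- textureMatrix(asDisc(gr), "glszm")$data
    o <- oracleGlszm(gr)
    z <- z[order(z$level, z$size), ]
    expect_equal(unname(as.matrix(z)), unname(as.matrix(o)),
                 info = paste("seed", seed))
  }
})

test_that("GLDM and NGTDM match their brute-force oracles", {
  for (seed in 1:10) {
    gr <- randomGrid(seed)
    expect_equal(unname(textureMatrix(asDisc(gr), "gldm")$data),
                 unname(oracleGldm(gr, max(gr))), info = paste("seed", seed))
    expect_equal(unname(textureMatrix(asDisc(gr), "ngtdm")$data),
                 unname(oracleNgtdm(gr, max(gr))), info = paste("seed", seed))
  }
})

test_that("constant regions give exact limit features, never NaN", {
  g <- array(1L, c(3, 3, 3))
  glcm <- textureFeatures(textureMatrix(asDisc(g), "glcm"))
  expect_length(glcm, 24)
  expect_equal(glcm[["Contrast"]], 0)
  expect_equal(glcm[["JointEntropy"]], 0)
  expect_equal(glcm[["JointEnergy"]], 1)
  expect_equal(glcm[["MaximumProbability"]], 1)
  expect_false(any(is.nan(glcm)))
  glrlm <- textureFeatures(textureMatrix(asDisc(g), "glrlm"))
  expect_length(glrlm, 16)
  # along each axis direction the cube is 9 runs of length 3
  expect_false(any(is.nan(glrlm)))
  expect_equal(glrlm[["GrayLevelVariance"]], 0)
  glszm <- textureFeatures(textureMatrix(asDisc(g), "glszm"))
  expect_length(glszm, 16)
  expect_equal(glszm[["ZonePercentage"]], 1 / 27) # one zone of 27 voxels
  gldm <- textureFeatures(textureMatrix(asDisc(g), "gldm"))
  expect_length(gldm, 14)
  ngtdm <- textureFeatures(textureMatrix(asDisc(g), "ngtdm"))
  expect_length(ngtdm, 5)
  expect_equal(ngtdm[["Contrast"]], 0)
  expect_false(any(is.nan(c(glszm, gldm, ngtdm))))
})

test_that("GLCM contrast and homogeneity agree with a direct double sum", {
  withr::with_seed(42, {
    g <- array(sample(1:4, 4^3, replace = TRUE), c(4, 4, 4))
  })
  tm <- textureMatrix(asDisc(g), "glcm")
  feats <- textureFeatures(tm)
  dirFeat <- function(C, f) {
    p <- C / sum(C)
    i <- row(p); j <- col(p)
    sum(f(i, j) * p)
  }
  ref <- rowMeans(vapply(seq_len(dim(tm$data)[3]), function(a) {
    C <- tm$data[, , a]
    c(contrast = dirFeat(C, function(i, j) (i - j)^2),
      id = dirFeat(C, function(i, j) 1 / (1 + abs(i - j))))
  }, numeric(2)))
  expect_equal(feats[["Contrast"]], ref[["contrast"]])
  expect_equal(feats[["Id"]], ref[["id"]])
})

test_that("run features on a known pattern: 9 runs of length 3 per axis", {
  g <- array(1L, c(3, 3, 3))
  tm <- textureMatrix(asDisc(g), "glrlm")
  axisDirs <- which(apply(oracleDirections(), 1, function(d) sum(abs(d))) == 1)
  for (a in axisDirs) {
    expect_equal(tm$data[1, 3, a], 9)
    expect_equal(sum(tm$data[, , a]), 9)
  }
})

test_that("feature family sizes reconcile to 93 per image", {
  g <- randomGrid(3)
  sizes <- vapply(c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                  function(k) length(textureFeatures(textureMatrix(asDisc(g), k))),
                  0L)
  expect_equal(unname(sizes), c(24L, 16L, 16L, 14L, 5L))
  expect_equal(18L + sum(sizes), 93L)
})
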