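test_that("generation is deterministic and label-blind at zero effect", {
  sp <- smallSpec(peritumoralEffect = 0)
  a <- generateCase(sp, "positive", seed = 5)
  b <- generateCase(sp, "positive", seed = 5)
  expect_identical(imageData(caseImage(a)), imageData(caseImage(b)))
  # zero planted effect: a positive case is voxel-identical to a negative
  n <- generateCase(sp, "negative", seed = 5)
  expect_identical(imageData(caseImage(a)), imageData(caseImage(n)))
  expect_identical(maskArray(caseCore(a)), maskArray(caseCore(n)))
})

test_that("positive cases differ from negatives only outside the core", {
  # noise-free phantoms so the only difference is the planted signal
  sp <- smallSpec(peritumoralEffect = 1, noiseSd = 0)
  p <- generateCase(sp, "positive", seed = 9)
  n <- generateCase(sp, "negative", seed = 9)
  coreM <- maskArray(caseCore(p))
  expect_identical(maskArray(caseCore(n)), coreM)
  dif <- imageData(caseImage(p)) - imageData(caseImage(n))
  expect_true(all(dif[coreM] == 0))   # intranodular voxels untouched
  expect_true(any(dif[!coreM] != 0))  # perinodular signal present
})

test_that("core voxel count tracks the analytic sphere volume", {
  sp <- phantomSpec(gridShape = c(72L, 72L, 72L), noduleDiameterMm = 20)
  for (seed in 1:5) {
    cs <- generateCase(sp, "negative", seed = seed)
    v <- voxelCount(caseCore(cs))
    expect_gt(v, 4 / 3 * pi * 10^3 * 0.75)
    expect_lt(v, 4 / 3 * pi * 10^3 * 1.25)
  }
})

test_that("a nodule that cannot honour the margin fails loudly", {
  sp <- phantomSpec(gridShape = c(48L, 48L, 48L), noduleDiameterMm = 20)
  expect_error(generateCase(sp, "negative", seed = 1), "margin")
})

test_that("composition respects the configured HU bands", {
  solid <- generateCase(smallSpec(ctr = 1, noiseSd = 10), "negative", 3)
  mSolid <- mean(imageData(caseImage(solid))[maskArray(caseCore(solid))])
  expect_gt(mSolid, 0)
  expect_lt(mSolid, 60)
  ggo <- generateCase(smallSpec(ctr = 0, noiseSd = 10), "negative", 3)
  mGgo <- mean(imageData(caseImage(ggo))[maskArray(caseCore(ggo))])
  expect_gt(mGgo, -600)
  expect_lt(mGgo, -300)
  # parenchyma sits near the configured lung HU
  lungOnly <- maskArray(caseLung(ggo)) &
    !maskArray(dilateMm(caseCore(ggo), 12))
  expect_equal(mean(imageData(caseImage(ggo))[lungOnly]), -800,
               tolerance = 0.01)
})

test_that("cohorts have the requested composition and reproducible seeds", {
  expect_length(generateCohort(0, 0, smallSpec(), seed = 1), 0)
  coh <- generateCohort(4, 9, smallSpec(), seed = 2)
  expect_length(coh, 13)
  labs <- vapply(coh, caseLabel, "")
  expect_equal(sum(labs == "positive"), 4)
  man <- attr(coh, "manifest")
  expect_equal(nrow(man), 13)
  expect_true(all(man$diameter_mm >= 8 & man$diameter_mm <= 32))
  expect_true(all(man$ctr >= 0 & man$ctr <= 1))
  # different master seeds give different voxels
  c1 <- generateCohort(1, 1, smallSpec(), seed = 10)
  c2 <- generateCohort(1, 1, smallSpec(), seed = 11)
  expect_false(identical(imageData(caseImage(c1[[1]])),
                         imageData(caseImage(c2[[1]]))))
  # identical master seeds reproduce bit-for-bit
  c3 <- generateCohort(1, 1, smallSpec(), seed = 10)
  expect_identical(imageData(caseImage(c1[[1]])), imageData(caseImage(c3[[1]])))
})

test_that("every generated case keeps core inside lung", {
  for (seed in 1:10) {
    cs <- generateCase(smallSpec(pleuralContactProb = 0.6),
                       "negative", seed)
    expect_true(all(maskArray(caseLung(cs))[maskArray(caseCore(cs))]))
    expect_gt(voxelCount(caseCore(cs)), 0)
  }
})

test_that("peritumoral shell statistics separate classes monotonically in effect", {
  # two-sample test on the 2-10 mm shell HU variance; rejection rate at
  # alpha = 0.05 should be near nominal at zero effect and rise steeply
  # with the planted effect size
  shellVar <- function(cs) {
    core <- caseCore(cs)
    vb <- peristas:::voiBoxes(maskArray(core), maskArray(caseLung(cs)),
                              spacing(core), distances = c(2, 10))
    img <- imageData(caseImage(cs))[vb$ix, vb$iy, vb$iz, drop = FALSE]
    ring <- vb$shells[["10"]] & !vb$shells[["2"]]
    var(img[ring])
  }
  rejRate <- function(eff, reps, nPer = 6, base = 0) {
    sp <- smallSpec(peritumoralEffect = eff)
    mean(vapply(seq_len(reps), function(r) {
      vp <- vapply(seq_len(nPer), function(i)
        shellVar(generateCase(sp, "positive",
                              peristas:::deriveSeed(base + r, i))), 0)
      vn <- vapply(seq_len(nPer), function(i)
        shellVar(generateCase(sp, "negative",
                              peristas:::deriveSeed(base + r, i + nPer))), 0)
      wilcox.test(vp, vn)$p.value < 0.05
    }, TRUE))
  }
  r0 <- rejRate(0, reps = 100)
  expect_lt(r0, 0.12) # type-I close to the nominal 5%
  r1 <- rejRate(1, reps = 15)
  expect_gt(r1, r0)
  expect_gt(r1, 0.9) # defaults give near-certain separation
})

test_that("streamed cohort features equal the materialized path", {
  sp <- smallSpec()
  fs1 <- simulateCohortFeatures(3, 4, sp, seed = 7)
  coh <- generateCohort(3, 4, sp, seed = 7)
  fs2 <- extractCohortFeatures(coh, families = "firstorder",
                               filters = "original")
  expect_identical(featureMatrix(fs1), featureMatrix(fs2))
  expect_identical(caseLabels(fs1), caseLabels(fs2))
})

test_that("cases round-trip through NIfTI", {
  cs <- generateCase(smallSpec(), "positive", seed = 13)
  dir <- withr::local_tempdir()
  writeCase(cs, dir)
  img <- readCtVolume(file.path(dir, "image.nii.gz"))
  expect_equal(imageData(img), imageData(caseImage(cs)), tolerance = 1e-6)
  expect_equal(spacing(img), spacing(caseImage(cs)))
  tum <- readMask(file.path(dir, "tumor.nii.gz"))
  expect_identical(maskArray(tum), maskArray(caseCore(cs)))
  coh <- generateCohort(1, 2, smallSpec(), seed = 3)
  writeCohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_true(all(c("case_id", "label", "seed", "diameter_mm", "ctr") %in%
                  colnames(man)))
})
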