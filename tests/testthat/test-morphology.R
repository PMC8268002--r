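test_that("dilation matches integer-offset enumeration on single voxels", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  # isotropic 1 mm, d = 2: offsets with dx^2+dy^2+dz^2 <= 4
  expect_equal(voxelCount(dilateMm(voxelMask(m), 2)), 33)
  # anisotropic (1,1,2) mm, d = 2: dx^2+dy^2+4dz^2 <= 4
  expect_equal(voxelCount(dilateMm(voxelMask(m, spacing = c(1, 1, 2)), 2)), 15)
})

test_that("dilation edge cases: identity at d = 0, negative d errors", {
  m <- array(runif(4^3) > 0.5, c(4, 4, 4))
  vm <- voxelMask(m)
  expect_identical(maskArray(dilateMm(vm, 0)), m)
  expect_identical(maskArray(erodeMm(vm, 0)), m)
  expect_error(dilateMm(vm, -1), "non-negative")
  expect_error(erodeMm(vm, -0.5), "non-negative")
})

test_that("erosion: thin objects vanish, cubes shrink exactly", {
  one <- array(FALSE, c(5, 5, 5))
  one[3, 3, 3] <- TRUE
  expect_equal(voxelCount(erodeMm(voxelMask(one), 1)), 0)
  cube <- array(FALSE, c(11, 11, 11))
  cube[3:9, 3:9, 3:9] <- TRUE
  er <- erodeMm(voxelMask(cube), 1)
  expect_equal(voxelCount(er), 125) # 7^3 -> 5^3
})

test_that("dilate/erode equal the brute-force distance oracle", {
  for (seed in 1:6) {
    m <- withr::with_seed(seed, array(runif(6 * 5 * 7) > 0.7, c(6, 5, 7)))
    if (!any(m)) m[1] <- TRUE
    for (sp in list(c(1, 1, 1), c(1, 1, 2.5), c(0.7, 1.3, 1))) {
      vm <- voxelMask(m, spacing = sp)
      for (d in c(1, 2, 3.3)) {
        expect_identical(maskArray(dilateMm(vm, d)), oracleDilate(m, d, sp))
        expect_identical(maskArray(erodeMm(vm, d)), oracleErode(m, d, sp))
      }
    }
  }
})

test_that("closing contains the original mask for digital balls", {
  co <- seq(-6, 6)
  for (r in c(2, 3.5, 5)) {
    ball <- outer(outer(co^2, co^2, "+"), co^2, "+") <= r^2
    vm <- voxelMask(ball)
    for (d in c(1, 2)) {
      cl <- erodeMm(dilateMm(vm, d), d)
      expect_true(all(maskArray(cl)[ball]))
    }
  }
})

test_that("perinodular shells are lung-clipped, core-disjoint and sized right", {
  lung <- voxelMask(array(TRUE, c(11, 11, 11)))
  core <- array(FALSE, c(11, 11, 11))
  core[6, 6, 6] <- TRUE
  core <- voxelMask(core)
  sh <- perinodularShell(core, lung, 2)
  expect_equal(voxelCount(sh), 32) # 33 dilated minus the core voxel
  expect_equal(sum(maskArray(sh) & maskArray(core)), 0)

  # core at the lung boundary: nothing leaks outside the lung
  lungHalf <- array(FALSE, c(11, 11, 11))
  lungHalf[1:6, , ] <- TRUE
  lungHalf <- voxelMask(lungHalf)
  shc <- perinodularShell(core, lungHalf, 3)
  expect_equal(sum(maskArray(shc) & !maskArray(lungHalf)), 0)
})

test_that("perinodular shell rejects inconsistent inputs", {
  lung <- voxelMask(array(FALSE, c(5, 5, 5)))
  core <- array(FALSE, c(5, 5, 5))
  core[3, 3, 3] <- TRUE
  expect_error(perinodularShell(voxelMask(core), lung, 2), "contained")
  expect_error(perinodularShell(voxelMask(array(FALSE, c(5, 5, 5))),
                                voxelMask(array(TRUE, c(5, 5, 5))), 2),
               "empty")
})

test_that("interface band spans both sides and swallows thin cores", {
  lung <- voxelMask(array(TRUE, c(15, 15, 15)))
  core <- array(FALSE, c(15, 15, 15))
  core[7:9, 7:9, 7:9] <- TRUE # 3 mm cube, thinner than 2 x 3 mm
  core <- voxelMask(core)
  band <- interfaceBand(core, lung) # default r = 3
  expect_true(all(maskArray(band)[maskArray(core)])) # erosion is empty
  expect_equal(sum(maskArray(band) & !maskArray(lung)), 0)
  # band equals dilate(core,3) & lung minus erode(core,3), by definition
  ref <- maskArray(dilateMm(core, 3)) & maskArray(lung) &
         !maskArray(erodeMm(core, 3))
  expect_identical(maskArray(band), ref)
})

test_that("buildVoiSet yields the eight nested, clipped, disjoint VOIs", {
  sp <- smallSpec()
  cs <- generateCase(sp, "positive", seed = 21)
  vs <- buildVoiSet(caseCore(cs), caseLung(cs))
  vl <- voiList(vs)
  expect_length(vl, 8)
  expect_named(vl, c("core", "s2", "s4", "s6", "s8", "s10", "s20", "band"))
  lungM <- maskArray(caseLung(cs))
  coreM <- maskArray(caseCore(cs))
  sizes <- vapply(vl[paste0("s", c(2, 4, 6, 8, 10, 20))], voxelCount, 1L)
  expect_true(all(diff(sizes) > 0)) # cumulative shells nest strictly here
  s2m <- maskArray(vl$s2)
  for (nm in setdiff(names(vl), "core")) {
    m <- maskArray(vl[[nm]])
    expect_equal(sum(m & !lungM), 0, info = nm)
    if (nm != "band") expect_equal(sum(m & coreM), 0, info = nm)
    expect_true(all(m[s2m]), info = nm) # every wider VOI contains the 2 mm shell
  }
  # the part of the band beyond the core within 2 mm is exactly the 2 mm shell
  expect_identical(maskArray(vl$band) & s2m, s2m)
})

test_that("buildVoiSet is a pure function of (core, lung, spacing)", {
  sp <- smallSpec()
  cs <- generateCase(sp, "negative", seed = 4)
  a <- buildVoiSet(caseCore(cs), caseLung(cs))
  b <- buildVoiSet(caseCore(cs), caseLung(cs))
  expect_identical(lapply(voiList(a), maskArray),
                   lapply(voiList(b), maskArray))
})

test_that("shell construction stays consistent on random phantoms", {
  for (seed in 101:120) {
    cs <- generateCase(smallSpec(pleuralContactProb = 0.5),
                       if (seed %% 2) "positive" else "negative", seed)
    vs <- buildVoiSet(caseCore(cs), caseLung(cs), distances = c(2, 6, 10))
    vl <- voiShells(vs)
    lungM <- maskArray(caseLung(cs))
    coreM <- maskArray(caseCore(cs))
    prev <- NULL
    for (nm in names(vl)) {
      m <- maskArray(vl[[nm]])
      expect_equal(sum(m & !lungM), 0)
      expect_equal(sum(m & coreM), 0)
      if (!is.null(prev)) expect_true(all(m[prev]))
      prev <- m
    }
  }
})
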