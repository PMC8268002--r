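# Synthetic CT phantoms. The generator emulates the cohort the analysis
# assumes: ~1 mm near-isotropic chest CT in HU, lung parenchyma around
# -800 HU inside two ellipsoidal lung fields, nodules with a solid core
# (CTR-controlled) and ground-glass halo, placed centrally or against the
# pleural boundary, and -- for STAS-positive cases only -- a perinodular
# signal confined to within 10 mm of the tumor surface: excess intensity
# heterogeneity, hyperdense 1-3 mm satellite micro-nodules, and blurring
# of the tumor-lung interface. With peritumoralEffect = 0 the positive
# branch is skipped entirely, so positive and negative cases with the same
# seed are voxel-identical.

#' Create a phantom specification
#'
#' Defaults reflect the emulated study conditions: mean nodule diameter
#' 19.7 mm (SD 6.2), CTR 0.7 (SD 0.3), 1 mm isotropic voxels, lung
#' parenchyma at -800 HU. The grid must be able to contain the nodule
#' plus a `marginMm` (20 mm) margin so the largest perinodular shell
#' never leaves the grid.
#'
#' @param gridShape integer(3), voxels per axis.
#' @param spacingMm numeric(3) or scalar, voxel size in mm.
#' @param lungHu,noiseSd parenchyma intensity and Gaussian noise SD (HU).
#' @param noduleDiameterMm,diameterSdMm lesion diameter distribution (mm).
#' @param ctr,ctrSd consolidation-to-tumor ratio distribution.
#' @param solidHu,ggoHu intensities of the solid and ground-glass
#'   components (HU).
#' @param peritumoralEffect effect size (>= 0) of the planted
#'   STAS-positive perinodular signal; 0 disables it.
#' @param pleuralContactProb probability of pleural contact.
#' @param marginMm required grid margin around the nodule (mm).
#' @return A [PhantomSpec].
#' @export
phantomSpec <- function(gridShape = c(96L, 84L, 84L),
                        spacingMm = c(1, 1, 1),
                        lungHu = -800, noiseSd = 30,
                        noduleDiameterMm = 19.7, diameterSdMm = 6.2,
                        ctr = 0.7, ctrSd = 0.3,
                        solidHu = 30, ggoHu = -450,
                        peritumoralEffect = 1,
                        pleuralContactProb = 0.25,
                        marginMm = 20) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), lungHu = lungHu, noiseSd = noiseSd,
      noduleDiameterMm = noduleDiameterMm, diameterSdMm = diameterSdMm,
      ctr = ctr, ctrSd = ctrSd, solidHu = solidHu, ggoHu = ggoHu,
      peritumoralEffect = peritumoralEffect,
      pleuralContactProb = pleuralContactProb, marginMm = marginMm)
}

# cache for the deterministic lung field (same for every case of a spec)
.peristasCache <- new.env(parent = emptyenv())

# per-case diameter / CTR draws of a cohort (truncated normals)
cohortDraws <- function(n, spec, seed) {
  withSeed(deriveSeed(seed, 0L), {
    dia <- pmin(pmax(rnorm(n, spec@noduleDiameterMm, spec@diameterSdMm), 8),
                32)
    ctr <- pmin(pmax(rnorm(n, spec@ctr, spec@ctrSd), 0), 1)
    list(dia = dia, ctr = ctr)
  })
}

# Two ellipsoidal lung fields inside the grid; returns list(mask, centres,
# semiAxes) with centres/semi-axes in physical mm. Deterministic.
lungField <- function(spec) {
  key <- paste(c(spec@gridShape, spec@spacingMm), collapse = "_")
  hit <- .peristasCache[[key]]
  if (!is.null(hit)) return(hit)
  ext <- spec@gridShape * spec@spacingMm
  semi <- c(0.19, 0.32, 0.40) * ext
  centres <- rbind(c(0.30 * ext[1], ext[2] / 2, ext[3] / 2),
                   c(0.70 * ext[1], ext[2] / 2, ext[3] / 2))
  cx <- axisCoords(spec@gridShape[1], spec@spacingMm[1])
  cy <- axisCoords(spec@gridShape[2], spec@spacingMm[2])
  cz <- axisCoords(spec@gridShape[3], spec@spacingMm[3])
  mask <- array(FALSE, spec@gridShape)
  for (l in 1:2) {
    qx <- ((cx - centres[l, 1]) / semi[1])^2
    qy <- ((cy - centres[l, 2]) / semi[2])^2
    qz <- ((cz - centres[l, 3]) / semi[3])^2
    mask <- mask | (outer(outer(qx, qy, "+"), qz, "+") <= 1)
  }
  out <- list(mask = mask, centres = centres, semi = semi,
              lungVm = voxelMask(mask, spec@spacingMm))
  .peristasCache[[key]] <- out
  out
}

# noise-free background image (soft-tissue body + lung parenchyma); the
# same for every case of a spec, so cached
baseImage <- function(spec, lf) {
  key <- paste(c("base", spec@gridShape, spec@spacingMm, spec@lungHu),
               collapse = "_")
  hit <- .peristasCache[[key]]
  if (is.null(hit)) {
    hit <- array(40, spec@gridShape)
    hit[lf$mask] <- spec@lungHu
    .peristasCache[[key]] <- hit
  }
  hit
}

# ellipsoid indicator on physical coordinate vectors
ellipsoidMask <- function(cx, cy, cz, centre, radii) {
  qx <- ((cx - centre[1]) / radii[1])^2
  qy <- ((cy - centre[2]) / radii[2])^2
  qz <- ((cz - centre[3]) / radii[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

#' Generate one labeled synthetic case
#'
#' Deterministic in `(spec, label, seed)`. For `label = "positive"` and
#' `peritumoralEffect > 0`, the perinodular field within 10 mm of the
#' tumor surface carries extra heterogeneity, Poisson-scattered 1-3 mm
#' hyperdense satellites, and an interface blur; otherwise it is pure
#' parenchyma plus noise.
#'
#' @param spec a [PhantomSpec].
#' @param label `"positive"` or `"negative"`.
#' @param seed integer seed.
#' @return A [LabeledCase].
#' @examples
#' sp <- phantomSpec(gridShape = c(72L, 72L, 72L), noduleDiameterMm = 12)
#' cs <- generateCase(sp, "negative", seed = 7)
#' voxelCount(caseCore(cs))
#' @export
generateCase <- function(spec, label = c("negative", "positive"), seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  label <- match.arg(label)
  R <- spec@noduleDiameterMm / 2
  ext <- spec@gridShape * spec@spacingMm
  clear <- R + spec@marginMm + max(spec@spacingMm)
  if (any(2 * clear >= ext))
    stop(sprintf(paste0("nodule (diameter %.1f mm) plus the %g mm margin ",
                        "does not fit in the grid (extent %s mm)"),
         2 * R, spec@marginMm, paste(format(ext), collapse = " x ")))

  lf <- lungField(spec)
  withSeed(seed, {
    # --- nodule placement ---------------------------------------------
    side <- if (runif(1) < 0.5) 1L else 2L
    L <- lf$centres[side, ]
    centre <- NULL
    pleural <- runif(1) < spec@pleuralContactProb
    if (pleural) {
      # walk a random direction to where the nodule surface grazes the
      # lung boundary; large nodules near the boundary often violate the
      # grid margin, in which case we fall back to central placement
      for (try in 1:100) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        rho <- 1 / sqrt(sum((u / lf$semi)^2)) # ellipsoid radius along u
        cand <- L + u * max(rho - 0.9 * R, 0)
        if (all(cand > clear) && all(cand < ext - clear)) {
          centre <- cand
          break
        }
      }
    }
    if (is.null(centre)) {
      for (try in 1:400) {
        cand <- runif(3, clear, ext - clear)
        q <- sqrt(sum(((cand - L) / lf$semi)^2))
        if (q <= 0.85) {
          centre <- cand
          break
        }
      }
    }
    if (is.null(centre))
      stop(sprintf("could not place the nodule inside the lung with a %g mm margin",
                   spec@marginMm))

    # mild axis anisotropy, volume-preserving (product of factors = 1)
    f <- runif(3, 0.85, 1.15)
    radii <- R * f / prod(f)^(1 / 3)
    # nodule voxels live in a small box around the centre: evaluate the
    # ellipsoids there only
    nlo <- pmax(floor((centre - radii) / spec@spacingMm) - 1, 0)
    nhi <- pmin(ceiling((centre + radii) / spec@spacingMm) + 1,
                spec@gridShape - 1)
    ixN <- (nlo[1]:nhi[1]) + 1L; iyN <- (nlo[2]:nhi[2]) + 1L
    izN <- (nlo[3]:nhi[3]) + 1L
    bx <- axisCoords(spec@gridShape[1], spec@spacingMm[1])[ixN]
    by <- axisCoords(spec@gridShape[2], spec@spacingMm[2])[iyN]
    bz <- axisCoords(spec@gridShape[3], spec@spacingMm[3])[izN]
    lungBox <- lf$mask[ixN, iyN, izN, drop = FALSE]
    coreBox <- ellipsoidMask(bx, by, bz, centre, radii) & lungBox
    solidBox <- if (spec@ctr > 0)
      ellipsoidMask(bx, by, bz, centre, pmax(radii * spec@ctr, 1e-6)) & coreBox
    else
      array(FALSE, dim(coreBox))
    coreMask <- array(FALSE, spec@gridShape)
    coreMask[ixN, iyN, izN] <- coreBox

    # --- image assembly ------------------------------------------------
    img <- baseImage(spec, lf)                  # body + parenchyma (cached)
    imgBox <- img[ixN, iyN, izN, drop = FALSE]
    imgBox[coreBox] <- spec@ggoHu
    imgBox[solidBox] <- spec@solidHu
    img[ixN, iyN, izN] <- imgBox

    if (label == "positive" && spec@peritumoralEffect > 0) {
      eff <- spec@peritumoralEffect
      # local distance field around the nodule
      bb <- boundingBoxRanges(coreMask, growBy = as.integer(
        ceiling(12 / min(spec@spacingMm))))
      sub <- coreMask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                      drop = FALSE]
      dOut <- array(.edt_mm(sub, dim(sub), spec@spacingMm), dim(sub))
      lungSub <- lf$mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                         bb$lo[3]:bb$hi[3], drop = FALSE]
      imgSub <- img[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                    drop = FALSE]
      shell10 <- dOut > 0 & dOut <= 10 & lungSub

      # satellite micro-nodules: hyperdense 1-3 mm blobs in the 10 mm shell
      nSat <- rpois(1, 6 * eff)
      if (nSat > 0 && any(shell10)) {
        shellIdx <- which(shell10)
        pick <- shellIdx[sample.int(length(shellIdx), min(nSat, length(shellIdx)))]
        dsub <- dim(sub)
        for (p in pick) {
          i <- (p - 1) %% dsub[1] + 1
          j <- ((p - 1) %/% dsub[1]) %% dsub[2] + 1
          k <- (p - 1) %/% (dsub[1] * dsub[2]) + 1
          sr <- runif(1, 0.5, 1.5)  # radius in mm
          rv <- ceiling(sr / spec@spacingMm) + 1
          li <- pmax(c(i, j, k) - rv, 1)
          hi <- pmin(c(i, j, k) + rv, dsub)
          bx <- (li[1]:hi[1] - i) * spec@spacingMm[1]
          by <- (li[2]:hi[2] - j) * spec@spacingMm[2]
          bz <- (li[3]:hi[3] - k) * spec@spacingMm[3]
          blob <- ellipsoidMask(bx, by, bz, c(0, 0, 0), rep(sr, 3)) &
                  shell10[li[1]:hi[1], li[2]:hi[2], li[3]:hi[3], drop = FALSE]
          tgt <- imgSub[li[1]:hi[1], li[2]:hi[2], li[3]:hi[3], drop = FALSE]
          tgt[blob] <- spec@solidHu - 10
          imgSub[li[1]:hi[1], li[2]:hi[2], li[3]:hi[3]] <- tgt
        }
      }

      # interface blur: smooth the +/-3 mm transition zone (computed on
      # the core bounding box grown just past the band width)
      bb2 <- boundingBoxRanges(sub, growBy = as.integer(
        ceiling(5 / min(spec@spacingMm))))
      jx <- bb2$lo[1]:bb2$hi[1]; jy <- bb2$lo[2]:bb2$hi[2]
      jz <- bb2$lo[3]:bb2$hi[3]
      blurred <- gaussianSmooth3d(imgSub[jx, jy, jz, drop = FALSE],
                                  0.8 * eff, spec@spacingMm)
      # strictly outside the core: the planted signal must stay
      # perinodular so the core-only model is handicapped by construction
      band <- (dOut <= 3 & dOut > 0) & lungSub
      bandBox <- band[jx, jy, jz, drop = FALSE]
      tgt <- imgSub[jx, jy, jz, drop = FALSE]
      tgt[bandBox] <- blurred[bandBox]
      imgSub[jx, jy, jz] <- tgt

      # excess heterogeneity in the perinodular field
      nSh <- sum(shell10)
      if (nSh > 0)
        imgSub[shell10] <- imgSub[shell10] + rnorm(nSh, 0, 15 * eff)

      img[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- imgSub
    }

    img <- img + rnorm(length(img), 0, spec@noiseSd)

    new("LabeledCase",
        image = ctVolume(img, spec@spacingMm),
        lung = lf$lungVm,
        core = voxelMask(coreMask, spec@spacingMm),
        label = label, seed = as.integer(seed))
  })
}

#' Generate a labeled synthetic cohort
#'
#' Case order is all positives first, then all negatives; per-case seeds
#' are derived reproducibly from the master seed, and per-case nodule
#' diameters and CTR values are drawn from the spec's truncated normal
#' distributions (diameter limited to [8, 32] mm, CTR to [0, 1]).
#'
#' @param nPos,nNeg class sizes (the emulated cohort is 56 / 160).
#' @param spec a [PhantomSpec].
#' @param seed master seed.
#' @return A list of [LabeledCase] objects with names `case001`, ...
#' @export
generateCohort <- function(nPos = 56, nNeg = 160, spec = phantomSpec(),
                           seed = 1L) {
  stopifnot(nPos >= 0, nNeg >= 0)
  n <- nPos + nNeg
  if (n == 0) return(list())
  labels <- rep(c("positive", "negative"), c(nPos, nNeg))
  draws <- cohortDraws(n, spec, seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    speci <- spec
    speci@noduleDiameterMm <- draws$dia[i]
    speci@ctr <- draws$ctr[i]
    out[[i]] <- generateCase(speci, labels[i], deriveSeed(seed, i))
  }
  names(out) <- sprintf("case%03d", seq_len(n))
  attr(out, "manifest") <- data.frame(
    case_id = names(out), label = labels,
    seed = vapply(seq_len(n), function(i) deriveSeed(seed, i), 1L),
    diameter_mm = draws$dia, ctr = draws$ctr)
  out
}

#' Simulate a cohort and extract its feature table in one stream
#'
#' Equivalent to `extractCohortFeatures(generateCohort(...))` — the same
#' per-case seeds, diameters and CTR draws — but cases are generated and
#' discarded one at a time, so memory stays flat for large cohorts.
#'
#' @inheritParams generateCohort
#' @inheritParams extractCohortFeatures
#' @return A [StasFeatureSet].
#' @export
simulateCohortFeatures <- function(nPos = 56, nNeg = 160,
                                   spec = phantomSpec(), seed = 1L,
                                   cfg = discretizationConfig(),
                                   families = "firstorder",
                                   filters = "original",
                                   distances = c(2, 4, 6, 8, 10, 20),
                                   bandMm = 3) {
  stopifnot(nPos + nNeg > 0)
  n <- nPos + nNeg
  labels <- rep(c("positive", "negative"), c(nPos, nNeg))
  draws <- cohortDraws(n, spec, seed)
  fast <- !"wavelet" %in% filters
  rows <- vector("list", n)
  excluded <- character(0)
  ids <- sprintf("case%03d", seq_len(n))
  for (i in seq_len(n)) {
    speci <- spec
    speci@noduleDiameterMm <- draws$dia[i]
    speci@ctr <- draws$ctr[i]
    cs <- generateCase(speci, labels[i], deriveSeed(seed, i))
    fv <- if (fast)
      caseFeaturesCropped(cs, cfg, families, distances, bandMm)
    else {
      vois <- buildVoiSet(caseCore(cs), caseLung(cs), distances, bandMm)
      extractMultiVoi(caseImage(cs), vois, cfg, families, filters)
    }
    if (length(attr(fv, "flagged"))) {
      message(sprintf("excluding %s: degenerate VOI(s) %s", ids[i],
                      paste(attr(fv, "flagged"), collapse = ", ")))
      excluded <- c(excluded, ids[i])
    } else rows[[i]] <- fv
  }
  keep <- !vapply(rows, is.null, TRUE)
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- ids[keep]
  fs <- stasFeatureSet(mat, labels[keep])
  metadata(fs)$excluded <- excluded
  fs
}

#' Write a case (or cohort) to NIfTI files
#'
#' Each case is written as `image.nii.gz`, `lung.nii.gz` and
#' `tumor.nii.gz` in its own directory; `writeCohort()` additionally
#' writes a `manifest.csv` (case_id, label, seed, diameter_mm, ctr)
#' where diameter and CTR are re-measured from the written core mask.
#'
#' @param case a [LabeledCase].
#' @param dir output directory (created if missing).
#' @export
writeCase <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCtVolume(caseImage(case), file.path(dir, "image.nii.gz"))
  writeMask(caseLung(case), file.path(dir, "lung.nii.gz"))
  writeMask(caseCore(case), file.path(dir, "tumor.nii.gz"))
  invisible(dir)
}

#' @rdname writeCase
#' @param cohort list of [LabeledCase] objects.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort)) writeCase(cohort[[nm]], file.path(dir, nm))
  manifest <- attr(cohort, "manifest")
  if (is.null(manifest))
    manifest <- data.frame(
      case_id = names(cohort),
      label = vapply(cohort, caseLabel, ""),
      seed = vapply(cohort, function(cs) cs@seed, 1L))
  manifest$n_core_voxels <-
    vapply(cohort, function(cs) sum(maskArray(caseCore(cs))), 1L)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
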