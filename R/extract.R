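# Feature-vector assembly. One VOI yields 851 features:
#   14 shape
# + 93 per image (18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM
#                 + 14 GLDM + 5 NGTDM)
# on the original image and on each of the 8 wavelet bands:
#   14 + 9 * 93 = 851.
# A case (8 VOIs) yields 8 * 851 = 6,808 features.

.allFamilies <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "gldm",
                  "ngtdm")
.textureFamilies <- c("glcm", "glrlm", "glszm", "gldm", "ngtdm")

# intensity + texture block for one (image, mask) pair
imageFamilies <- function(img, msk, cfg, families, spacing) {
  out <- numeric(0)
  if ("firstorder" %in% families)
    out <- c(out, prefixNames("firstorder",
                              firstOrderFeatures(img, msk, cfg, spacing)))
  tex <- intersect(.textureFamilies, families)
  if (length(tex)) {
    disc <- discretize(img, msk, cfg)
    for (fam in tex)
      out <- c(out, prefixNames(fam, textureFeatures(textureMatrix(disc, fam))))
  }
  out
}

prefixNames <- function(prefix, x) {
  names(x) <- paste(prefix, names(x), sep = "_")
  x
}

#' Extract the radiomic feature vector of one VOI
#'
#' With the default families and filters this returns the full
#' 851-feature vector: 14 shape descriptors plus 93 intensity/texture
#' features on the original image and on each of the eight wavelet
#' bands. The computation is cropped to the mask bounding box (grown by
#' a fixed 8-voxel pad) purely for speed; feature names and order are
#' fixed and the result is deterministic.
#'
#' @param image a [CtVolume].
#' @param mask a [VoxelMask] with at least 2 voxels.
#' @param cfg a [discretizationConfig()].
#' @param families subset of
#'   `c("shape","firstorder","glcm","glrlm","glszm","gldm","ngtdm")`.
#' @param filters subset of `c("original", "wavelet")`.
#' @return Named numeric vector (length 851 for the defaults).
#' @export
extractFeatureVector <- function(image, mask, cfg = discretizationConfig(),
                                 families = .allFamilies,
                                 filters = c("original", "wavelet")) {
  stopifnot(is(image, "CtVolume"), is(mask, "VoxelMask"))
  stopifnotGeometry(image, mask, "image and mask")
  families <- match.arg(families, .allFamilies, several.ok = TRUE)
  filters <- match.arg(filters, c("original", "wavelet"), several.ok = TRUE)
  if (voxelCount(mask) < 2L)
    stop("mask has fewer than 2 voxels; texture is undefined")

  bb <- boundingBoxRanges(mask@mask, growBy = 8L)
  img <- image@data[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                    drop = FALSE]
  msk <- mask@mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                   drop = FALSE]
  sp <- image@spacing

  out <- numeric(0)
  if ("shape" %in% families)
    out <- c(out, prefixNames("shape", shapeFeatures(msk, spacing = sp)))
  if ("original" %in% filters)
    out <- c(out, prefixNames("original",
                              imageFamilies(img, msk, cfg,
                                            setdiff(families, "shape"), sp)))
  if ("wavelet" %in% filters &&
      length(setdiff(families, "shape"))) {
    bands <- waveletBands(img)
    for (bn in names(bands))
      out <- c(out, prefixNames(paste0("wavelet.", bn),
                                imageFamilies(bands[[bn]], msk, cfg,
                                              setdiff(families, "shape"), sp)))
  }
  out
}

#' Extract the case-level feature vector across all eight VOIs
#'
#' Concatenates [extractFeatureVector()] over the VOIs of a [VoiSet] in
#' the fixed order core, shells by increasing distance, interface band;
#' names are prefixed with the VOI id (`core__`, `s2__`, ..., `band__`).
#' A VOI that is empty or smaller than 2 voxels gets an `NA` block and
#' is reported in the `"flagged"` attribute so the case can be excluded
#' downstream with a logged reason.
#'
#' @param image a [CtVolume].
#' @param vois a [VoiSet].
#' @inheritParams extractFeatureVector
#' @return Named numeric vector (length 6,808 for the defaults) with
#'   attribute `flagged` (character vector of degenerate VOI ids).
#' @export
extractMultiVoi <- function(image, vois, cfg = discretizationConfig(),
                            families = .allFamilies,
                            filters = c("original", "wavelet")) {
  stopifnot(is(vois, "VoiSet"))
  vl <- voiList(vois)
  flagged <- character(0)
  blocks <- vector("list", length(vl))
  template <- NULL
  for (vi in seq_along(vl)) {
    m <- vl[[vi]]
    if (voxelCount(m) >= 2L) {
      blocks[[vi]] <- extractFeatureVector(image, m, cfg, families, filters)
      if (is.null(template)) template <- names(blocks[[vi]])
    } else {
      flagged <- c(flagged, names(vl)[vi])
      blocks[[vi]] <- NA # placeholder, sized once the template is known
    }
  }
  if (is.null(template))
    stop("every VOI of the case is degenerate (< 2 voxels)")
  for (vi in seq_along(blocks))
    if (length(blocks[[vi]]) == 1L && is.na(blocks[[vi]][1]))
      blocks[[vi]] <- setNames(rep(NA_real_, length(template)), template)
  names(blocks) <- names(vl)
  out <- unlist(lapply(names(vl), function(nm)
    setNames(blocks[[nm]],
             paste(nm, names(blocks[[nm]]), sep = "__"))))
  attr(out, "flagged") <- flagged
  out
}

#' Extract features for a whole cohort into a StasFeatureSet
#'
#' Builds the VOI set of every case ([buildVoiSet()]) and extracts the
#' case-level feature vector. Cases with degenerate VOIs are excluded
#' (with a message) and listed in `metadata(x)$excluded`.
#'
#' @param cohort list of [LabeledCase] objects (see [generateCohort()]).
#' @inheritParams extractFeatureVector
#' @param distances shell distances in mm.
#' @param bandMm interface band half-width in mm.
#' @return A [StasFeatureSet].
#' @export
extractCohortFeatures <- function(cohort, cfg = discretizationConfig(),
                                  families = .allFamilies,
                                  filters = c("original", "wavelet"),
                                  distances = c(2, 4, 6, 8, 10, 20),
                                  bandMm = 3) {
  stopifnot(length(cohort) > 0)
  rows <- vector("list", length(cohort))
  excluded <- character(0)
  fast <- !"wavelet" %in% filters
  for (ci in seq_along(cohort)) {
    cs <- cohort[[ci]]
    fv <- if (fast) {
      caseFeaturesCropped(cs, cfg, families, distances, bandMm)
    } else {
      vois <- buildVoiSet(caseCore(cs), caseLung(cs), distances, bandMm)
      extractMultiVoi(caseImage(cs), vois, cfg, families, filters)
    }
    if (length(attr(fv, "flagged"))) {
      message(sprintf("excluding %s: degenerate VOI(s) %s",
                      names(cohort)[ci],
                      paste(attr(fv, "flagged"), collapse = ", ")))
      excluded <- c(excluded, names(cohort)[ci])
      rows[[ci]] <- NULL
    } else {
      rows[[ci]] <- fv
    }
  }
  keep <- !vapply(rows, is.null, TRUE)
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- names(cohort)[keep]
  fs <- stasFeatureSet(mat, vapply(cohort, caseLabel, "")[keep])
  metadata(fs)$excluded <- excluded
  fs
}

# Cropped-box extraction used when no wavelet filter is requested. All
# non-wavelet features depend only on the masked voxel values / mask
# geometry, so they can be computed on the shared VOI bounding box; the
# result is identical to extractMultiVoi() on full-grid masks.
caseFeaturesCropped <- function(cs, cfg, families, distances, bandMm) {
  core <- caseCore(cs)
  vb <- voiBoxes(core@mask, maskArray(caseLung(cs)), core@spacing,
                 distances, bandMm)
  img <- imageData(caseImage(cs))[vb$ix, vb$iy, vb$iz, drop = FALSE]
  sp <- core@spacing
  vl <- c(list(core = vb$core), vb$shells, list(band = vb$band))
  names(vl) <- c("core", paste0("s", names(vb$shells)), "band")
  flagged <- character(0)
  blocks <- lapply(names(vl), function(nm) {
    m <- vl[[nm]]
    if (sum(m) < 2L) {
      flagged <<- c(flagged, nm)
      return(NA)
    }
    out <- numeric(0)
    if ("shape" %in% families)
      out <- c(out, prefixNames("shape", shapeFeatures(m, spacing = sp)))
    out <- c(out, prefixNames("original",
                              imageFamilies(img, m, cfg,
                                            setdiff(families, "shape"), sp)))
    out
  })
  names(blocks) <- names(vl)
  template <- NULL
  for (b in blocks) if (!identical(b, NA)) { template <- names(b); break }
  if (is.null(template))
    stop("every VOI of the case is degenerate (< 2 voxels)")
  for (nm in names(blocks))
    if (identical(blocks[[nm]], NA))
      blocks[[nm]] <- setNames(rep(NA_real_, length(template)), template)
  out <- unlist(lapply(names(vl), function(nm)
    setNames(blocks[[nm]], paste(nm, names(blocks[[nm]]), sep = "__"))))
  attr(out, "flagged") <- flagged
  out
}
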