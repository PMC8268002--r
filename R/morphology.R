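# Millimetre-accurate binary morphology. Dilation and erosion are realized
# by thresholding an exact Euclidean distance transform (computed with
# physical spacing) rather than by iterating structuring elements, so a
# distance of d mm means the same thing on anisotropic grids as on
# isotropic ones. Distances are measured voxel-centre to voxel-centre and
# voxels at exactly d are included.

# distance (mm) of every voxel to the nearest TRUE voxel of m
distanceToMask <- function(m) {
  array(.edt_mm(m@mask, dim(m@mask), m@spacing), dim(m@mask))
}

# inclusive distance threshold with a relative epsilon so voxels at
# exactly d mm stay included under floating-point spacing arithmetic
distTol <- function(d) d + 1e-9 * (d + 1)

#' Dilate or erode a mask by a physical distance
#'
#' `dilateMm(mask, d)` returns all voxels whose Euclidean distance (mm,
#' spacing-aware) to the nearest mask voxel centre is at most `d`, i.e.
#' the mask grown by `d` mm. `erodeMm(mask, d)` is its dual: the voxels
#' whose distance to the mask complement exceeds `d`. `d = 0` is the
#' identity for both.
#'
#' @param mask a [VoxelMask].
#' @param d distance in mm, `>= 0`.
#' @return A [VoxelMask] with the same geometry.
#' @examples
#' m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
#' voxelCount(dilateMm(voxelMask(m), 2))  # 33 voxels
#' @export
dilateMm <- function(mask, d) {
  stopifnot(is(mask, "VoxelMask"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("'d' must be a single non-negative distance in mm")
  if (d == 0 || !any(mask@mask)) return(mask)
  voxelMask(distanceToMask(mask) <= distTol(d), mask@spacing, mask@origin)
}

#' @rdname dilateMm
#' @export
erodeMm <- function(mask, d) {
  stopifnot(is(mask, "VoxelMask"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("'d' must be a single non-negative distance in mm")
  if (d == 0) return(mask)
  comp <- voxelMask(!mask@mask, mask@spacing, mask@origin)
  voxelMask(mask@mask & distanceToMask(comp) > distTol(d), mask@spacing, mask@origin)
}

#' Perinodular shell at a given distance from the tumor surface
#'
#' The cumulative shell from the tumor surface out to `d` mm: the core
#' dilated by `d`, clipped to the lung field (so no extrapulmonary voxel
#' is ever included), minus the core itself. Shells at increasing
#' distances are nested.
#'
#' @param core [VoxelMask], the intranodular VOI; must be non-empty and
#'   contained in `lung`.
#' @param lung [VoxelMask], the lung field.
#' @param d outward distance in mm, `> 0`.
#' @return A [VoxelMask].
#' @export
perinodularShell <- function(core, lung, d) {
  checkCoreLung(core, lung)
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("'d' must be a single positive distance in mm")
  grown <- dilateMm(core, d)
  voxelMask(grown@mask & lung@mask & !core@mask, core@spacing, core@origin)
}

#' Tumor-lung interface band
#'
#' The band spanning `r` mm inside and outside the core contour:
#' `(dilate(core, r) & lung) \ erode(core, r)`. With the default band
#' half-width of 3 mm this is the 3 mm tumor shell plus the 3 mm
#' peripheral rim.
#' For cores thinner than `2r` the erosion is empty and the band covers
#' the whole core.
#'
#' @inheritParams perinodularShell
#' @param r band half-width in mm (default 3).
#' @return A [VoxelMask].
#' @export
interfaceBand <- function(core, lung, r = 3) {
  checkCoreLung(core, lung)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a single positive distance in mm")
  outer <- dilateMm(core, r)
  inner <- erodeMm(core, r)
  voxelMask(outer@mask & lung@mask & !inner@mask, core@spacing, core@origin)
}

#' Annular perinodular ring between two distances
#'
#' Utility: the ring strictly between `inner` and `outer` mm from the
#' tumor surface, i.e. the set difference of the two cumulative shells.
#'
#' @inheritParams perinodularShell
#' @param inner,outer ring bounds in mm, `0 <= inner < outer`.
#' @export
annularRing <- function(core, lung, inner, outer) {
  stopifnot(inner >= 0, outer > inner)
  big <- perinodularShell(core, lung, outer)
  if (inner == 0) return(big)
  small <- perinodularShell(core, lung, inner)
  voxelMask(big@mask & !small@mask, core@spacing, core@origin)
}

#' Build the full VOI set of a case
#'
#' Constructs the eight VOIs used throughout the package: the core,
#' cumulative perinodular shells at the given distances (default 2, 4, 6,
#' 8, 10, 20 mm) and the tumor-lung interface band (default +/- 3 mm).
#' Purely deterministic in (core, lung, spacing). An empty shell (core
#' filling the lung locally) is kept as an empty mask with a warning.
#'
#' @inheritParams perinodularShell
#' @param distances shell distances in mm, increasing.
#' @param bandMm interface band half-width in mm.
#' @return A [VoiSet].
#' @export
buildVoiSet <- function(core, lung, distances = c(2, 4, 6, 8, 10, 20),
                        bandMm = 3) {
  checkCoreLung(core, lung)
  vb <- voiBoxes(core@mask, lung@mask, core@spacing, distances, bandMm)
  d <- dim(core@mask)
  asFull <- function(subMask) {
    full <- array(FALSE, d)
    full[vb$ix, vb$iy, vb$iz] <- subMask
    voxelMask(full, core@spacing, core@origin)
  }
  shells <- lapply(vb$shells, asFull)
  names(shells) <- as.character(distances)
  new("VoiSet", core = core, shells = shells, interface = asFull(vb$band),
      bandMm = bandMm)
}

# The shared workhorse: all morphology lives within max(distances, bandMm)
# of the core, so the distance transforms are computed on the grown core
# bounding box only. Returns box index ranges and the VOI masks cropped to
# that box.
voiBoxes <- function(coreMask, lungMask, spacing,
                     distances = c(2, 4, 6, 8, 10, 20), bandMm = 3) {
  if (is.unsorted(distances, strictly = TRUE) || any(distances <= 0))
    stop("'distances' must be strictly increasing positive values")
  dmax <- max(distances, bandMm)
  grow <- as.integer(ceiling(dmax / min(spacing))) + 2L
  bb <- boundingBoxRanges(coreMask, growBy = grow)
  ix <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; iz <- bb$lo[3]:bb$hi[3]
  sub <- coreMask[ix, iy, iz, drop = FALSE]
  lungSub <- lungMask[ix, iy, iz, drop = FALSE]
  dOut <- array(.edt_mm(sub, dim(sub), spacing), dim(sub))
  # the inward distance is only needed on core voxels: transform the
  # core bounding box (plus one ring of complement) instead of the full box
  cb <- boundingBoxRanges(sub, growBy = 1L)
  jx <- cb$lo[1]:cb$hi[1]; jy <- cb$lo[2]:cb$hi[2]; jz <- cb$lo[3]:cb$hi[3]
  coreBox <- sub[jx, jy, jz, drop = FALSE]
  dInBox <- array(.edt_mm(!coreBox, dim(coreBox), spacing), dim(coreBox))
  dIn <- array(Inf, dim(sub))
  dIn[jx, jy, jz] <- dInBox
  peri <- dOut > 0 & lungSub
  shells <- lapply(distances, function(dd) {
    sh <- peri & dOut <= distTol(dd)
    if (!any(sh))
      warning(sprintf("shell at %g mm is empty (core fills the local lung field)", dd))
    sh
  })
  names(shells) <- as.character(distances)
  # band = (dilate(core, r) & lung) \ erode(core, r)
  band <- (dOut <= distTol(bandMm) & lungSub) & !(sub & dIn > distTol(bandMm))
  list(ix = ix, iy = iy, iz = iz, core = sub, lung = lungSub,
       shells = shells, band = band)
}

checkCoreLung <- function(core, lung) {
  stopifnot(is(core, "VoxelMask"), is(lung, "VoxelMask"))
  stopifnotGeometry(core, lung, "core and lung")
  inLung <- lung@mask[core@mask]
  if (!length(inLung)) stop("core mask is empty")
  if (!all(inLung))
    stop("core mask is not contained in the lung mask")
  invisible(TRUE)
}
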