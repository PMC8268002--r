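#' Construct a CtVolume
#'
#' @param data 3D numeric array of intensities (HU).
#' @param spacing voxel size in mm per axis (length 1 or 3).
#' @param origin world coordinate of the first voxel centre (mm).
#' @return A [CtVolume].
#' @examples
#' v <- ctVolume(array(rnorm(8 * 8 * 8, -800, 30), c(8, 8, 8)))
#' spacing(v)
#' @export
ctVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CtVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a VoxelMask
#'
#' @param mask 3D logical (or coercible) array.
#' @param spacing voxel size in mm per axis (length 1 or 3).
#' @param origin world coordinate of the first voxel centre (mm).
#' @return A [VoxelMask].
#' @export
voxelMask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  new("VoxelMask", mask = mask, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname peristas-accessors
#' @export
setMethod("spacing", "CtVolume", function(x, ...) x@spacing)
#' @rdname peristas-accessors
#' @export
setMethod("spacing", "VoxelMask", function(x, ...) x@spacing)
#' @rdname peristas-accessors
#' @export
setMethod("origin", "CtVolume", function(x, ...) x@origin)
#' @rdname peristas-accessors
#' @export
setMethod("origin", "VoxelMask", function(x, ...) x@origin)
#' @rdname peristas-accessors
#' @export
setMethod("imageData", "CtVolume", function(x, ...) x@data)
#' @rdname peristas-accessors
#' @export
setMethod("maskArray", "VoxelMask", function(x, ...) x@mask)
#' @rdname peristas-accessors
#' @export
setMethod("voxelCount", "VoxelMask", function(x, ...) sum(x@mask))
#' @rdname peristas-accessors
#' @export
setMethod("dim", "CtVolume", function(x) dim(x@data))
#' @rdname peristas-accessors
#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@mask))

#' @rdname peristas-accessors
#' @export
setMethod("voiCore", "VoiSet", function(x, ...) x@core)
#' @rdname peristas-accessors
#' @export
setMethod("voiShells", "VoiSet", function(x, ...) x@shells)
#' @rdname peristas-accessors
#' @export
setMethod("voiInterface", "VoiSet", function(x, ...) x@interface)

#' @rdname peristas-accessors
#' @details `voiList()` returns the VOIs as a flat named list in the fixed
#'   extraction order: core, shells by increasing distance, interface band.
#' @export
setMethod("voiList", "VoiSet", function(x, ...) {
  out <- c(list(core = x@core), x@shells, list(band = x@interface))
  names(out) <- c("core",
                  paste0("s", names(x@shells)),
                  "band")
  out
})

#' @rdname peristas-accessors
#' @export
setMethod("caseImage", "LabeledCase", function(x, ...) x@image)
#' @rdname peristas-accessors
#' @export
setMethod("caseLung", "LabeledCase", function(x, ...) x@lung)
#' @rdname peristas-accessors
#' @export
setMethod("caseCore", "LabeledCase", function(x, ...) x@core)
#' @rdname peristas-accessors
#' @export
setMethod("caseLabel", "LabeledCase", function(x, ...) x@label)

setMethod("show", "CtVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CtVolume %d x %d x %d, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("VoxelMask %d x %d x %d, spacing %s mm, %d voxels (%.1f mm^3)\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              sum(object@mask), sum(object@mask) * prod(object@spacing)))
})

setMethod("show", "VoiSet", function(object) {
  vl <- voiList(object)
  cat(sprintf("VoiSet with %d VOIs (band half-width %g mm)\n",
              length(vl), object@bandMm))
  for (nm in names(vl))
    cat(sprintf("  %-8s %d voxels\n", nm, sum(vl[[nm]]@mask)))
})

setMethod("show", "LabeledCase", function(object) {
  cat(sprintf("LabeledCase (STAS %s, seed %d): ", object@label, object@seed))
  show(object@image)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: grid %s, spacing %s mm\n",
    "  lung %g HU, noise SD %g HU, nodule %g +/- %g mm, CTR %g +/- %g\n",
    "  solid %g HU, ground-glass %g HU, peritumoral effect %g, pleural contact p=%g\n"),
    paste(object@gridShape, collapse = "x"),
    paste(object@spacingMm, collapse = "x"),
    object@lungHu, object@noiseSd, object@noduleDiameterMm,
    object@diameterSdMm, object@ctr, object@ctrSd, object@solidHu,
    object@ggoHu, object@peritumoralEffect, object@pleuralContactProb))
})

# geometry agreement between containers, with a small tolerance on spacing
sameGeometry <- function(a, b) {
  da <- if (is(a, "CtVolume")) dim(a@data) else dim(a@mask)
  db <- if (is(b, "CtVolume")) dim(b@data) else dim(b@mask)
  identical(da, db) &&
    all(abs(a@spacing - b@spacing) < 1e-9) &&
    all(abs(a@origin - b@origin) < 1e-6)
}

stopifnotGeometry <- function(a, b, what = "masks") {
  if (!sameGeometry(a, b))
    stop(sprintf("geometry mismatch between %s (dims/spacing/origin differ)",
                 what), call. = FALSE)
  invisible(TRUE)
}
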