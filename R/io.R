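#' Read / write CT volumes and masks as NIfTI-1
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' move pixel spacing in and out of the NIfTI header. Masks are stored as
#' uint8 volumes with values 0/1.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readCtVolume()` a [CtVolume]; `readMask()` a [VoxelMask].
#' @export
readCtVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ctVolume(array(as.numeric(img), dim(img)),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readCtVolume
#' @param x a [CtVolume] or [VoxelMask] to write.
#' @export
writeCtVolume <- function(x, path) {
  a <- x@data
  attr(a, "pixdim") <- x@spacing
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' @rdname readCtVolume
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  voxelMask(array(as.numeric(img) > 0.5, dim(img)),
            spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readCtVolume
#' @export
writeMask <- function(x, path) {
  a <- array(as.integer(x@mask), dim(x@mask))
  attr(a, "pixdim") <- x@spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), path)
  invisible(path)
}
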