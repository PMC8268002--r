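#' Gray-level discretization settings
#'
#' Fixed-bin-width discretization anchored at the VOI minimum:
#' `level(x) = floor((x - min) / binWidth) + 1`. Anchoring at the minimum
#' makes every discretized texture feature invariant to global intensity
#' shifts. The default bin width of 25 HU is common chest-CT radiomics
#' practice.
#'
#' @param binWidth width of one gray-level bin, in the image's intensity
#'   units (HU); `> 0`.
#' @param resegmentRange optional length-2 numeric: intensities are
#'   clamped into this range before binning.
#' @return A `discretizationConfig` object.
#' @export
discretizationConfig <- function(binWidth = 25, resegmentRange = NULL) {
  stopifnot(is.numeric(binWidth), length(binWidth) == 1L, binWidth > 0)
  if (!is.null(resegmentRange))
    stopifnot(length(resegmentRange) == 2L,
              resegmentRange[1] < resegmentRange[2])
  structure(list(binWidth = binWidth, resegmentRange = resegmentRange),
            class = "discretizationConfig")
}

#' Discretize a VOI to integer gray levels
#'
#' @param image a [CtVolume] (or bare 3D numeric array).
#' @param mask a [VoxelMask] (or bare 3D logical array) of the same shape;
#'   must be non-empty.
#' @param cfg a [discretizationConfig()].
#' @return A `discretizedGrid`: list with `grid` (integer array, 0 outside
#'   the mask, 1..nLevels inside), `nLevels`, and `dims`.
#' @export
discretize <- function(image, mask, cfg = discretizationConfig()) {
  img <- if (is(image, "CtVolume")) image@data else image
  msk <- if (is(mask, "VoxelMask")) mask@mask else mask
  stopifnot(identical(dim(img), dim(msk)))
  if (!any(msk)) stop("cannot discretize an empty mask")
  vals <- img[msk]
  if (!is.null(cfg$resegmentRange))
    vals <- pmin(pmax(vals, cfg$resegmentRange[1]), cfg$resegmentRange[2])
  lev <- as.integer(floor((vals - min(vals)) / cfg$binWidth)) + 1L
  grid <- array(0L, dim(img))
  grid[msk] <- lev
  structure(list(grid = grid, nLevels = max(lev), dims = dim(img)),
            class = "discretizedGrid")
}
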