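#' First-order intensity statistics of a VOI
#'
#' The 18 standard first-order features. Entropy and uniformity are
#' computed on the discretized histogram (see [discretizationConfig()]);
#' everything else on the raw intensities. Variance, skewness and
#' kurtosis are population moments; kurtosis is not excess-corrected.
#' Degenerate (constant) regions follow limit conventions: entropy 0,
#' uniformity 1, skewness and kurtosis 0 — never `NaN`.
#'
#' @param image a [CtVolume] or 3D numeric array.
#' @param mask a [VoxelMask] or 3D logical array; non-empty.
#' @param cfg a [discretizationConfig()] for the histogram features.
#' @param spacing voxel spacing in mm (taken from `image` when it is a
#'   [CtVolume]); needed for total energy.
#' @return Named numeric vector of length 18.
#' @examples
#' img <- array(c(1, 2, 3, 4, 0, 0, 0, 0), c(2, 2, 2))
#' msk <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
#' firstOrderFeatures(img, msk)[c("Mean", "Variance")]  # 2.5, 1.25
#' @export
firstOrderFeatures <- function(image, mask, cfg = discretizationConfig(),
                               spacing = NULL) {
  img <- if (is(image, "CtVolume")) image@data else image
  if (is.null(spacing))
    spacing <- if (is(image, "CtVolume")) image@spacing else c(1, 1, 1)
  msk <- if (is(mask, "VoxelMask")) mask@mask else mask
  stopifnot(identical(dim(img), dim(msk)))
  x <- img[msk]
  if (!length(x)) stop("cannot compute first-order features of an empty mask")

  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inner <- x[x >= q[1] & x <= q[5]]

  # histogram probabilities on the discretized levels
  vals <- x
  if (!is.null(cfg$resegmentRange))
    vals <- pmin(pmax(vals, cfg$resegmentRange[1]), cfg$resegmentRange[2])
  lev <- floor((vals - min(vals)) / cfg$binWidth) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]

  c(Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
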