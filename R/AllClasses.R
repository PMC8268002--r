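#' CtVolume: a 3D CT image in Hounsfield units
#'
#' A scalar 3D grid of CT attenuation values (HU) together with its voxel
#' spacing (mm per voxel along each axis) and world origin. All spatial
#' operations in the package are spacing-aware, so anisotropic
#' reconstructions are handled correctly.
#'
#' @slot data 3D numeric array of intensities (HU).
#' @slot spacing numeric(3), voxel size in mm along each axis; strictly
#'   positive.
#' @slot origin numeric(3), world coordinate of the first voxel centre (mm).
#' @export
setClass("CtVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("CtVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' VoxelMask: a binary region sharing a CtVolume's geometry
#'
#' Logical 3D grid marking a region (lung field, tumor core, perinodular
#' shell, ...). Masks carry their own spacing/origin so geometric
#' consistency between image and masks can be verified.
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot origin numeric(3), world coordinate of the first voxel centre (mm).
#' @export
setClass("VoxelMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' VoiSet: the eight volumes of interest of one case
#'
#' Container for the named VOIs built from a nodule (core) mask and a lung
#' mask: the core itself, cumulative perinodular shells at a set of
#' distances from the tumor surface (default 2, 4, 6, 8, 10 and 20 mm),
#' and the tumor-lung interface band spanning a fixed margin inside and
#' outside the core contour (default +/- 3 mm). All members share one
#' geometry and are clipped to the lung field.
#'
#' @slot core [VoxelMask] the intranodular VOI.
#' @slot shells named list of [VoxelMask], one cumulative shell per
#'   distance; names are the distances in mm.
#' @slot interface [VoxelMask] the tumor-lung interface band.
#' @slot bandMm half-width of the interface band in mm.
#' @export
setClass("VoiSet",
  representation(core = "VoxelMask", shells = "list",
                 interface = "VoxelMask", bandMm = "numeric"))

setValidity("VoiSet", function(object) {
  if (!all(vapply(object@shells, is, TRUE, "VoxelMask")))
    return("all shells must be VoxelMask objects")
  if (is.null(names(object@shells)) ||
      any(is.na(suppressWarnings(as.numeric(names(object@shells))))))
    return("shells must be named by their distance in mm")
  dims <- dim(object@core@mask)
  ok <- vapply(object@shells, function(s) identical(dim(s@mask), dims), TRUE)
  if (!all(ok) || !identical(dim(object@interface@mask), dims))
    return("all VOIs must share one grid geometry")
  if (length(object@bandMm) != 1L || object@bandMm <= 0)
    return("bandMm must be a single positive value")
  TRUE
})

#' PhantomSpec: parameters of the synthetic CT phantom generator
#'
#' Describes the study conditions emulated by the phantom generator: a
#' near-isotropic CT-like volume with lung parenchyma around -800 HU, a
#' nodule with a solid core and a ground-glass halo whose proportion is
#' set by the consolidation-to-tumor ratio (CTR), optional pleural
#' contact, and a plantable perinodular signal for STAS-positive cases
#' (excess heterogeneity, interface blurring and hyperdense satellite
#' micro-nodules within 10 mm of the tumor surface).
#'
#' Cohort-level draws use `noduleDiameterMm`/`diameterSdMm` and
#' `ctr`/`ctrSd` as the mean/SD of truncated normal distributions; a
#' single case generated directly from the spec uses the means as-is.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot spacingMm numeric(3) voxel size, mm.
#' @slot lungHu lung parenchyma intensity, HU.
#' @slot noiseSd additive Gaussian noise SD, HU.
#' @slot noduleDiameterMm mean lesion diameter, mm.
#' @slot diameterSdMm SD of the cohort diameter distribution, mm.
#' @slot ctr consolidation-to-tumor ratio in [0, 1].
#' @slot ctrSd SD of the cohort CTR distribution.
#' @slot solidHu intensity of the solid component, HU.
#' @slot ggoHu intensity of the ground-glass component, HU.
#' @slot peritumoralEffect effect-size scalar (>= 0) of the planted
#'   STAS-positive perinodular signal; 0 disables it.
#' @slot pleuralContactProb probability that a nodule is placed against
#'   the lung boundary.
#' @slot marginMm grid margin that must accommodate the largest
#'   perinodular dilation (mm).
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingMm = "numeric",
                 lungHu = "numeric", noiseSd = "numeric",
                 noduleDiameterMm = "numeric", diameterSdMm = "numeric",
                 ctr = "numeric", ctrSd = "numeric",
                 solidHu = "numeric", ggoHu = "numeric",
                 peritumoralEffect = "numeric",
                 pleuralContactProb = "numeric", marginMm = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be 3 integers >= 8")
  if (any(object@spacingMm <= 0) || length(object@spacingMm) != 3L)
    return("spacingMm must be 3 strictly positive values")
  if (object@ctr < 0 || object@ctr > 1) return("ctr must lie in [0, 1]")
  if (object@peritumoralEffect < 0)
    return("peritumoralEffect must be >= 0")
  if (object@pleuralContactProb < 0 || object@pleuralContactProb > 1)
    return("pleuralContactProb must lie in [0, 1]")
  if (object@noduleDiameterMm <= 0) return("noduleDiameterMm must be > 0")
  TRUE
})

#' LabeledCase: one synthetic patient record
#'
#' Image, lung mask, nodule (core) mask and STAS label of one generated
#' case, plus the seed it was generated from.
#'
#' @slot image [CtVolume].
#' @slot lung [VoxelMask], the lung field.
#' @slot core [VoxelMask], the nodule; always a subset of the lung.
#' @slot label `"positive"` or `"negative"` STAS status.
#' @slot seed integer seed the case was generated from.
#' @export
setClass("LabeledCase",
  representation(image = "CtVolume", lung = "VoxelMask", core = "VoxelMask",
                 label = "character", seed = "integer"))

setValidity("LabeledCase", function(object) {
  if (!object@label %in% c("positive", "negative"))
    return("label must be 'positive' or 'negative'")
  d <- dim(object@image@data)
  if (!identical(dim(object@lung@mask), d) ||
      !identical(dim(object@core@mask), d))
    return("image, lung and core must share one grid")
  inLung <- object@lung@mask[object@core@mask]
  if (!length(inLung)) return("core mask is empty")
  if (!all(inLung))
    return("core must be contained in the lung mask")
  TRUE
})

#' StasFeatureSet: cases-by-features radiomics table
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding radiomic feature
#' values (features as rows, cases as columns) with the binary STAS label
#' in `colData`. Standardisation parameters fitted on training data are
#' kept in `metadata(x)$zscore` so held-out tables can be transformed
#' consistently.
#'
#' @export
setClass("StasFeatureSet", contains = "SummarizedExperiment")

setValidity("StasFeatureSet", function(object) {
  if (!"label" %in% colnames(colData(object)))
    return("colData must contain a 'label' column")
  lab <- colData(object)$label
  if (length(lab) && !all(lab %in% c("positive", "negative")))
    return("labels must be 'positive'/'negative'")
  TRUE
})
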