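#' @name peristas-accessors
#' @title Accessors for imaging containers
#'
#' @description Slot access for [CtVolume], [VoxelMask], [VoiSet] and
#' [LabeledCase] objects goes through these generics; user code should
#' never reach into slots directly.
#'
#' @param x the object.
#' @param ... unused.
NULL

#' @rdname peristas-accessors
#' @export
setGeneric("spacing", function(x, ...) standardGeneric("spacing"))

#' @rdname peristas-accessors
#' @export
setGeneric("origin", function(x, ...) standardGeneric("origin"))

#' @rdname peristas-accessors
#' @export
setGeneric("imageData", function(x, ...) standardGeneric("imageData"))

#' @rdname peristas-accessors
#' @export
setGeneric("maskArray", function(x, ...) standardGeneric("maskArray"))

#' @rdname peristas-accessors
#' @export
setGeneric("voxelCount", function(x, ...) standardGeneric("voxelCount"))

#' @rdname peristas-accessors
#' @export
setGeneric("voiCore", function(x, ...) standardGeneric("voiCore"))

#' @rdname peristas-accessors
#' @export
setGeneric("voiShells", function(x, ...) standardGeneric("voiShells"))

#' @rdname peristas-accessors
#' @export
setGeneric("voiInterface", function(x, ...) standardGeneric("voiInterface"))

#' @rdname peristas-accessors
#' @export
setGeneric("voiList", function(x, ...) standardGeneric("voiList"))

#' @rdname peristas-accessors
#' @export
setGeneric("caseImage", function(x, ...) standardGeneric("caseImage"))

#' @rdname peristas-accessors
#' @export
setGeneric("caseLung", function(x, ...) standardGeneric("caseLung"))

#' @rdname peristas-accessors
#' @export
setGeneric("caseCore", function(x, ...) standardGeneric("caseCore"))

#' @rdname peristas-accessors
#' @export
setGeneric("caseLabel", function(x, ...) standardGeneric("caseLabel"))

#' @rdname peristas-accessors
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname peristas-accessors
#' @export
setGeneric("caseLabels", function(x, ...) standardGeneric("caseLabels"))
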