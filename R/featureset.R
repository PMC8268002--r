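#' Construct a StasFeatureSet
#'
#' @param values cases-by-features numeric matrix (row names = case ids).
#' @param labels character vector (`"positive"`/`"negative"`), one per case.
#' @return A [StasFeatureSet] (features stored as rows, cases as columns,
#'   following SummarizedExperiment convention).
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("case", 1:4), paste0("f", 1:5)))
#' fs <- stasFeatureSet(m, c("positive", "positive", "negative", "negative"))
#' dim(featureMatrix(fs))
#' @export
stasFeatureSet <- function(values, labels) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("case%03d", seq_len(nrow(values)))
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    colData = DataFrame(label = as.character(labels),
                        row.names = rownames(values)))
  new("StasFeatureSet", se)
}

#' @rdname peristas-accessors
#' @export
setMethod("featureMatrix", "StasFeatureSet", function(x, ...) t(assay(x)))

#' @rdname peristas-accessors
#' @export
setMethod("caseLabels", "StasFeatureSet",
          function(x, ...) colData(x)$label)

# replace the value matrix, keeping labels/metadata
setFeatureMatrix <- function(x, values) {
  out <- stasFeatureSet(values, caseLabels(x))
  metadata(out) <- metadata(x)
  out
}

# convenience subset by case index
subsetCases <- function(x, idx) {
  out <- stasFeatureSet(featureMatrix(x)[idx, , drop = FALSE],
                        caseLabels(x)[idx])
  metadata(out) <- metadata(x)
  out
}

setMethod("show", "StasFeatureSet", function(object) {
  lab <- caseLabels(object)
  cat(sprintf("StasFeatureSet: %d cases x %d features (%d positive, %d negative)\n",
              ncol(object), nrow(object),
              sum(lab == "positive"), sum(lab == "negative")))
})
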