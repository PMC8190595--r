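#' ExpressionMatrix: a gene-by-sample expression matrix
#'
#' Container for expression values with unique gene and sample identifiers
#' and an explicit statement of what the numbers are: raw `counts`
#' (RNA-seq), fluorescence `intensity` (microarray), or within-sample
#' percentile `rank` values in \[0, 1\] as produced by [rankTransform()].
#' Missing values are represented as `NA` and treated as an explicit mask
#' throughout: a missing entry never contributes to ranks, variance
#' decompositions or projections.
#'
#' @slot values Numeric gene-by-sample matrix; rownames are gene ids,
#'   colnames are sample ids.
#' @slot valueKind Character scalar, one of `"counts"`, `"intensity"`,
#'   `"rank"`.
#'
#' @seealso [readMatrix()], [rankTransform()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", valueKind = "character"))

.validExpressionMatrix <- function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@valueKind) != 1L ||
      !object@valueKind %in% c("counts", "intensity", "rank"))
    msg <- c(msg, "'valueKind' must be one of counts, intensity, rank")
  fin <- v[!is.na(v)]
  if (length(fin) && any(fin < 0))
    msg <- c(msg, "negative expression values are not allowed")
  if (identical(object@valueKind, "rank") && length(fin) && any(fin > 1))
    msg <- c(msg, "rank values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required (gene and sample identifiers).
#' @param valueKind `"counts"`, `"intensity"` or `"rank"`.
#' @return A validated [ExpressionMatrix-class].
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, valueKind = c("counts", "intensity", "rank")) {
  valueKind <- match.arg(valueKind)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, valueKind = valueKind)
}

#' AtlasModel: a frozen PCA reference atlas
#'
#' The fitted atlas: the platform-robust gene set, per-gene mean ranks used
#' for centering, orthonormal PCA loadings, reference sample coordinates,
#' the sample annotation table, per-gene platform-variance statistics and
#' the frozen build configuration. Queries are mapped into this frame by
#' [projectSamples()]; the frame itself is never refit.
#'
#' @slot geneIds Character vector of retained (filtered) gene ids.
#' @slot geneMeans Named numeric vector: per-gene mean rank over reference
#'   samples.
#' @slot loadings Gene-by-K orthonormal loading matrix.
#' @slot explainedVariance Length-K non-increasing numeric vector.
#' @slot coords Sample-by-K reference coordinates.
#' @slot sampleTable `data.frame` of reference sample annotations.
#' @slot geneStats `data.frame` of per-gene filter statistics (all genes
#'   considered, not only those kept).
#' @slot config Named list of frozen build parameters.
#' @seealso [buildAtlas()], [saveAtlas()], [loadAtlas()]
#' @export
setClass("AtlasModel",
  representation(geneIds = "character", geneMeans = "numeric",
                 loadings = "matrix", explainedVariance = "numeric",
                 coords = "matrix", sampleTable = "data.frame",
                 geneStats = "data.frame", config = "list"))

.validAtlasModel <- function(object) {
  msg <- character()
  G <- length(object@geneIds)
  K <- ncol(object@loadings)
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (nrow(object@loadings) != G)
    msg <- c(msg, "loadings must have one row per retained gene")
  if (length(object@geneMeans) != G)
    msg <- c(msg, "geneMeans length must match retained genes")
  if (length(object@explainedVariance) != K)
    msg <- c(msg, "explainedVariance length must equal number of components")
  if (is.unsorted(rev(object@explainedVariance)))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (ncol(object@coords) != K)
    msg <- c(msg, "coords must have one column per component")
  if (K > 0 && G > 0) {
    gram <- crossprod(object@loadings)
    if (max(abs(gram - diag(K))) > 1e-8)
      msg <- c(msg, "loading columns must be orthonormal (tol 1e-8)")
  }
  if (nrow(object@coords) != nrow(object@sampleTable))
    msg <- c(msg, "coords and sampleTable must describe the same samples")
  if (length(msg)) msg else TRUE
}
setValidity("AtlasModel", .validAtlasModel)

#' ProjectionResult: query samples mapped into an atlas frame
#'
#' @slot coords Query-by-K coordinate matrix.
#' @slot coverage Numeric in \[0, 1\]: fraction of atlas genes measured in
#'   each query sample; imputed (mean-substituted) genes count against it.
#' @slot warnings Character vector of per-projection warnings (e.g. low
#'   coverage).
#' @seealso [projectSamples()]
#' @export
setClass("ProjectionResult",
  representation(coords = "matrix", coverage = "numeric",
                 warnings = "character"))

setValidity("ProjectionResult", function(object) {
  msg <- character()
  if (length(object@coverage) != nrow(object@coords))
    msg <- c(msg, "one coverage value per query sample required")
  if (length(object@coverage) &&
      (any(object@coverage < 0) || any(object@coverage > 1)))
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(object@coords) && any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' CentroidSet: per-cell-type mean rank profiles
#'
#' Mean rank vector over the atlas genes for each reference cell type (or
#' any other annotation grouping), used for correlation similarity and
#' simplex identity weights. Types built from fewer than three reference
#' samples are flagged low-confidence.
#'
#' @slot centroids Atlas-gene-by-type matrix of mean ranks in \[0, 1\].
#' @slot nSamples Integer vector: reference samples per type.
#' @slot lowConfidence Logical vector: fewer than three reference samples.
#' @seealso [buildCentroids()], [similarityScores()], [capybaraWeights()]
#' @export
setClass("CentroidSet",
  representation(centroids = "matrix", nSamples = "integer",
                 lowConfidence = "logical"))

setValidity("CentroidSet", function(object) {
  msg <- character()
  k <- ncol(object@centroids)
  if (length(object@nSamples) != k || length(object@lowConfidence) != k)
    msg <- c(msg, "per-type metadata must match number of centroids")
  if (any(object@nSamples < 1L))
    msg <- c(msg, "every centroid needs at least one reference sample")
  v <- object@centroids[!is.na(object@centroids)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    msg <- c(msg, "centroid values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
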