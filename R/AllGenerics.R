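#' @import methods
NULL

#' Gene identifiers of an object
#'
#' @param x An object holding genes (an [ExpressionMatrix-class],
#'   [AtlasModel-class] or [CentroidSet-class]).
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#'
#' @param x An object holding samples.
#' @return Character vector of sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Kind of values stored in an expression matrix
#'
#' One of `"counts"`, `"intensity"` or `"rank"`.
#'
#' @param x An [ExpressionMatrix-class].
#' @return Character scalar.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' Numeric values of an expression matrix
#'
#' @param x An [ExpressionMatrix-class].
#' @return Gene-by-sample numeric matrix (missing entries are `NA`).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Reference or projected coordinates
#'
#' @param x An [AtlasModel-class] or [ProjectionResult-class].
#' @return Sample-by-component numeric matrix.
#' @export
setGeneric("atlasCoords", function(x) standardGeneric("atlasCoords"))

#' PCA gene loadings of an atlas
#'
#' @param x An [AtlasModel-class].
#' @return Gene-by-component orthonormal matrix.
#' @export
setGeneric("atlasLoadings", function(x) standardGeneric("atlasLoadings"))

#' Per-component explained variance
#'
#' @param x An [AtlasModel-class].
#' @return Non-increasing numeric vector.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' Sample annotation table
#'
#' @param x An [AtlasModel-class].
#' @return A `data.frame` with one row per reference sample (see
#'   [readAnnotations()] for the schema).
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' Per-gene platform-variance statistics
#'
#' @param x An [AtlasModel-class].
#' @return A `data.frame` with columns `gene_id`, `platform_fraction`,
#'   `n_datasets_measured`, `kept` (see [filterGenes()]).
#' @export
setGeneric("geneStats", function(x) standardGeneric("geneStats"))

#' Frozen build configuration of an atlas
#'
#' @param x An [AtlasModel-class].
#' @return Named list of the parameters the atlas was built with.
#' @export
setGeneric("atlasConfig", function(x) standardGeneric("atlasConfig"))

#' Per-query coverage of the atlas gene set
#'
#' @param x A [ProjectionResult-class].
#' @return Numeric vector in \[0, 1\], one entry per query sample.
#' @export
setGeneric("geneCoverage", function(x) standardGeneric("geneCoverage"))
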