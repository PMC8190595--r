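#' @describeIn ExpressionMatrix gene identifiers
#' @param x,object An `ExpressionMatrix`.
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn ExpressionMatrix sample identifiers
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn ExpressionMatrix value kind (`counts`/`intensity`/`rank`)
#' @export
setMethod("valueKind", "ExpressionMatrix", function(x) x@valueKind)

#' @describeIn ExpressionMatrix the numeric matrix
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn ExpressionMatrix dimensions (genes, samples)
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(v), ncol(v), object@valueKind))
  if (anyNA(v))
    cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(v)),
                100 * mean(is.na(v))))
})

#' @describeIn AtlasModel retained gene identifiers
#' @param x,object An `AtlasModel`.
#' @export
setMethod("geneIds", "AtlasModel", function(x) x@geneIds)

#' @describeIn AtlasModel reference sample identifiers
#' @export
setMethod("sampleIds", "AtlasModel", function(x) rownames(x@coords))

#' @describeIn AtlasModel reference coordinates (samples x K)
#' @export
setMethod("atlasCoords", "AtlasModel", function(x) x@coords)

#' @describeIn AtlasModel orthonormal gene loadings (genes x K)
#' @export
setMethod("atlasLoadings", "AtlasModel", function(x) x@loadings)

#' @describeIn AtlasModel per-component explained variance
#' @export
setMethod("explainedVariance", "AtlasModel", function(x) x@explainedVariance)

#' @describeIn AtlasModel reference sample annotations
#' @export
setMethod("sampleTable", "AtlasModel", function(x) x@sampleTable)

#' @describeIn AtlasModel per-gene filter statistics
#' @export
setMethod("geneStats", "AtlasModel", function(x) x@geneStats)

#' @describeIn AtlasModel frozen build parameters
#' @export
setMethod("atlasConfig", "AtlasModel", function(x) x@config)

setMethod("show", "AtlasModel", function(object) {
  K <- ncol(object@loadings)
  ev <- object@explainedVariance
  cat(sprintf("AtlasModel: %d genes, %d reference samples, K = %d\n",
              length(object@geneIds), nrow(object@coords), K))
  if (sum(ev) > 0)
    cat(sprintf("  explained variance share: %s\n",
                paste(sprintf("PC%d %.1f%%", seq_len(K),
                              100 * ev / sum(ev)), collapse = ", ")))
  ct <- object@sampleTable$cell_type
  if (!is.null(ct))
    cat(sprintf("  cell types: %s\n",
                paste(names(sort(table(ct), decreasing = TRUE)),
                      collapse = ", ")))
})

#' @describeIn ProjectionResult projected coordinates (queries x K)
#' @param x,object A `ProjectionResult`.
#' @export
setMethod("atlasCoords", "ProjectionResult", function(x) x@coords)

#' @describeIn ProjectionResult query sample identifiers
#' @export
setMethod("sampleIds", "ProjectionResult", function(x) rownames(x@coords))

#' @describeIn ProjectionResult fraction of atlas genes measured per query
#' @export
setMethod("geneCoverage", "ProjectionResult", function(x) x@coverage)

setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf("ProjectionResult: %d query samples in %d components\n",
              nrow(object@coords), ncol(object@coords)))
  cat(sprintf("  atlas gene coverage: median %.2f, min %.2f\n",
              stats::median(object@coverage), min(object@coverage)))
  for (w in object@warnings) cat("  warning:", w, "\n")
})

#' @describeIn CentroidSet atlas gene identifiers
#' @param x,object A `CentroidSet`.
#' @export
setMethod("geneIds", "CentroidSet", function(x) rownames(x@centroids))

#' Cell types represented in a CentroidSet
#'
#' @param x A [CentroidSet-class].
#' @return Character vector of type labels.
#' @export
cellTypes <- function(x) {
  stopifnot(is(x, "CentroidSet"))
  colnames(x@centroids)
}

#' @describeIn CentroidSet the gene-by-type centroid matrix
#' @export
setMethod("exprValues", "CentroidSet", function(x) x@centroids)

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d types over %d atlas genes\n",
              ncol(object@centroids), nrow(object@centroids)))
  info <- sprintf("%s (n=%d%s)", colnames(object@centroids),
                  object@nSamples,
                  ifelse(object@lowConfidence, ", low-confidence", ""))
  cat(" ", paste(info, collapse = "; "), "\n")
})
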