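#' Per-sample percentile-rank transformation
#'
#' Replaces each sample's expression values by within-sample percentile
#' ranks across genes: `r = (rank - 0.5) / n`, where `rank` is the average
#' rank (ties share their average) and `n` is the number of genes measured
#' in that sample. The transform is invariant to any strictly increasing
#' per-sample function of the values — log scaling, CPM/TPM normalization
#' and monotone platform response curves all map to the same ranks — which
#' is what makes samples from different platforms directly comparable.
#' A constant sample maps to 0.5 everywhere, and a tie-free sample's
#' column is a permutation of `(i - 0.5)/n`, so every column has mean 0.5.
#'
#' Missing entries stay missing and are excluded from `n` for that
#' sample.
#'
#' @param m An [ExpressionMatrix-class] of kind `counts` or `intensity`.
#' @return An [ExpressionMatrix-class] of kind `rank`, same shape and ids.
#' @examples
#' m <- ExpressionMatrix(matrix(c(3, 1, 2), 3, 1,
#'        dimnames = list(c("a", "b", "c"), "s1")), "counts")
#' exprValues(rankTransform(m))  # 0.833, 0.167, 0.5
#' @export
rankTransform <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (valueKind(m) == "rank")
    stop("matrix is already rank-transformed")
  v <- exprValues(m)
  nMeasured <- colSums(!is.na(v))
  if (any(nMeasured < 2L))
    stop("sample(s) with fewer than 2 measured genes: ",
         paste(colnames(v)[nMeasured < 2L], collapse = ", "))
  r <- apply(v, 2L, function(col) {
    (rank(col, ties.method = "average", na.last = "keep") - 0.5) /
      sum(!is.na(col))
  })
  dimnames(r) <- dimnames(v)
  ExpressionMatrix(r, "rank")
}
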