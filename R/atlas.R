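#' Build a PCA reference atlas from rank-transformed samples
#'
#' Restricts the rank matrix to the genes kept by [filterGenes()],
#' centers each gene at its mean rank over the reference samples, and
#' computes a K-component PCA by singular value decomposition. The
#' loading sign is fixed deterministically (each component's
#' largest-magnitude loading is made positive) so that rebuilding the
#' same atlas is bit-comparable. Reference coordinates are
#' `t(L) %*% (r_s - mu)` for each sample's rank vector `r_s`; any missing
#' entry of a reference sample is mean-imputed (contributing zero after
#' centering).
#'
#' @param r Rank-transformed [ExpressionMatrix-class] of reference
#'   samples.
#' @param annot Annotation `data.frame` covering all samples of `r`.
#' @param stats Per-gene filter table from [filterGenes()]; only genes
#'   with `kept == TRUE` enter the atlas.
#' @param K Number of principal components to retain (default 3, matching
#'   the 2D/3D displays the atlas is meant for).
#' @param config Optional named list of extra parameters to freeze into
#'   the model (e.g. `theta`, `minDatasetFrac`, `seed`).
#' @return An [AtlasModel-class].
#' @export
buildAtlas <- function(r, annot, stats, K = 3L, config = list()) {
  stopifnot(is(r, "ExpressionMatrix"), valueKind(r) == "rank",
            is.data.frame(stats), K >= 1L)
  annot <- .checkSampleCoverage(sampleIds(r), annot)
  keep <- stats$gene_id[stats$kept]
  keep <- intersect(rownames(exprValues(r)), keep)
  if (length(keep) < K)
    stop("need at least K kept genes; have ", length(keep))
  v <- exprValues(r)[keep, , drop = FALSE]
  S <- ncol(v)
  if (S < K + 1L)
    stop("need at least K + 1 samples; have ", S)

  mu <- rowMeans(v, na.rm = TRUE)
  x <- v - mu
  x[is.na(x)] <- 0  # mean imputation of masked entries
  sv <- svd(x, nu = min(K, S - 1L), nv = min(K, S - 1L))
  achievableK <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1L])
  if (K > min(achievableK, S - 1L))
    stop("K = ", K, " exceeds the rank of the centered matrix; ",
         "achievable K is ", min(achievableK, S - 1L))
  L <- sv$u[, seq_len(K), drop = FALSE]
  d <- sv$d[seq_len(K)]
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(K)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  coords <- crossprod(x, L)
  dimnames(L) <- list(keep, paste0("PC", seq_len(K)))
  dimnames(coords) <- list(colnames(v), paste0("PC", seq_len(K)))
  ev <- d^2 / (S - 1L)

  cfg <- utils::modifyList(
    list(K = K, rank_convention = "(average rank - 0.5) / n_measured",
         duplicate_gene_policy = "per-sample max",
         n_reference_samples = S, n_atlas_genes = length(keep)),
    config)
  new("AtlasModel", geneIds = keep, geneMeans = mu, loadings = L,
      explainedVariance = ev, coords = coords, sampleTable = annot,
      geneStats = stats, config = cfg)
}

#' Project external samples onto a frozen atlas
#'
#' Queries are rank-transformed over their own full measured gene set
#' (never re-ranked after subsetting, so a sample's position does not
#' depend discontinuously on the atlas gene list), subset to the atlas
#' genes, and mapped as `t(L) %*% (r - mu)`. Atlas genes absent from a
#' query are imputed at the atlas mean rank `mu` — contributing zero
#' after centering — and counted against that query's coverage. There is
#' no re-centering on the query dataset: this is benchmarking against a
#' frozen frame, not co-embedding.
#'
#' @param model An [AtlasModel-class].
#' @param m Query [ExpressionMatrix-class]; `counts`/`intensity` values
#'   are rank-transformed first, `rank` values are used as-is.
#' @return A [ProjectionResult-class]. A warning is recorded (and raised)
#'   for queries covering less than half of the atlas genes.
#' @export
projectSamples <- function(model, m) {
  stopifnot(is(model, "AtlasModel"), is(m, "ExpressionMatrix"))
  shared <- intersect(geneIds(m), model@geneIds)
  if (length(shared) == 0L)
    stop("query shares no gene identifiers with the atlas")
  r <- if (valueKind(m) == "rank") m else rankTransform(m)
  v <- exprValues(r)

  G <- length(model@geneIds)
  q <- matrix(model@geneMeans, nrow = G, ncol = ncol(v),
              dimnames = list(model@geneIds, colnames(v)))
  hit <- v[match(model@geneIds, rownames(v)), , drop = FALSE]
  present <- !is.na(hit)
  q[present] <- hit[present]
  coverage <- colMeans(present)

  coords <- crossprod(q - model@geneMeans, model@loadings)
  warnings <- character()
  low <- coverage < 0.5
  if (any(low)) {
    warnings <- sprintf("sample %s covers only %.0f%% of atlas genes",
                        colnames(v)[low], 100 * coverage[low])
    for (w in warnings) warning(w)
  }
  new("ProjectionResult", coords = coords,
      coverage = unname(coverage), warnings = warnings)
}

#' Summarize one atlas axis by an annotation grouping
#'
#' Per-group median and spread of a chosen principal-component
#' coordinate, for quantifying statements like "cultured monocytes sit
#' away from in vivo monocytes along PC3". When exactly two groups are
#' present a two-sided Wilcoxon rank-sum p-value for a coordinate shift
#' between them is attached as attribute `rank_sum_p`.
#'
#' @param model An [AtlasModel-class].
#' @param axis Component index (1-based, at most K).
#' @param groupBy Name of a column of the model's sample table, e.g.
#'   `"sample_source"` or `"cell_type"`.
#' @return `data.frame`: group, n, median, q25, q75, min, max.
#' @export
axisSummary <- function(model, axis = 1L, groupBy = "sample_source") {
  stopifnot(is(model, "AtlasModel"))
  if (axis < 1L || axis > ncol(model@coords))
    stop("axis must be between 1 and K = ", ncol(model@coords))
  st <- model@sampleTable
  if (!groupBy %in% names(st))
    stop("unknown annotation field: ", groupBy)
  x <- model@coords[, axis]
  g <- as.character(st[[groupBy]])
  out <- do.call(rbind, lapply(split(x, g), function(xs) {
    qs <- stats::quantile(xs, c(0.25, 0.75), names = FALSE)
    data.frame(n = length(xs), median = stats::median(xs),
               q25 = qs[1L], q75 = qs[2L], min = min(xs), max = max(xs))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  if (length(unique(g)) == 2L) {
    sp <- split(x, g)
    attr(out, "rank_sum_p") <-
      stats::wilcox.test(sp[[1L]], sp[[2L]], exact = FALSE)$p.value
  }
  out
}
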