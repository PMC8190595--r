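#' Build per-cell-type centroids from atlas reference samples
#'
#' For each level of an annotation field (cell type by default), the
#' centroid is the per-gene mean rank over that level's reference
#' samples, restricted to the atlas genes. Levels with fewer than three
#' samples are flagged low-confidence but retained.
#'
#' Reference rank values are reconstructed from the stored atlas
#' coordinates and loadings (`mu + L c_s`), i.e. the K-component
#' representation the atlas itself works in.
#'
#' @param model An [AtlasModel-class].
#' @param by Annotation column to group by (default `"cell_type"`).
#' @return A [CentroidSet-class].
#' @export
buildCentroids <- function(model, by = "cell_type") {
  stopifnot(is(model, "AtlasModel"))
  st <- model@sampleTable
  if (!by %in% names(st)) stop("unknown annotation field: ", by)
  g <- as.character(st[[by]])
  if (all(is.na(g)) || length(g) == 0L) stop("annotation field '", by, "' is empty")
  # reconstruct rank profiles in the atlas's K-dim representation
  ranks <- model@geneMeans + model@loadings %*% t(model@coords)
  lev <- sort(unique(g))
  cm <- vapply(lev, function(l)
    rowMeans(ranks[, g == l, drop = FALSE]), numeric(nrow(ranks)))
  cm <- pmin(pmax(cm, 0), 1)  # clip K-truncation overshoot to rank range
  dimnames(cm) <- list(model@geneIds, lev)
  n <- as.integer(table(factor(g, levels = lev)))
  new("CentroidSet", centroids = cm, nSamples = n, lowConfidence = n < 3L)
}

#' Correlation similarity of queries to cell-type centroids
#'
#' Pearson correlation of each query rank vector against each centroid
#' over the shared atlas genes, after removing the average reference
#' profile (each gene's mean across centroids) from both sides — the
#' "similarity score" coloring used when comparing projected clusters to
#' reference cell types. Correlating deviations from the average profile
#' rather than raw rank vectors stops the component all cell types share
#' (housekeeping expression) from pushing every score toward one: a
#' query equal to centroid `k` scores exactly 1 against it, and a query
#' whose deviations are the mirror image of centroid `k`'s scores
#' exactly -1. The call is the best-correlated type.
#'
#' @param centroids A [CentroidSet-class].
#' @param query Rank matrix (genes x queries) or a rank-kind
#'   [ExpressionMatrix-class]; a bare vector is treated as one query.
#' @return A score table `data.frame`: `query_id`, one column of
#'   correlations in \[-1, 1\] per type, and `call`.
#' @export
similarityScores <- function(centroids, query) {
  q <- .asQueryMatrix(query, centroids)
  shared <- rownames(q)
  if (length(shared) < 3L)
    stop("need at least 3 genes shared with the centroids")
  C <- exprValues(centroids)[shared, , drop = FALSE]
  mu <- rowMeans(C)
  qc <- q - mu
  bad <- apply(q, 2L, stats::sd) == 0 | apply(qc, 2L, stats::sd) == 0
  if (any(bad))
    stop("zero-variance query over shared genes: ",
         paste(colnames(q)[bad], collapse = ", "))
  sc <- stats::cor(qc, C - mu)
  call <- colnames(C)[max.col(sc, ties.method = "first")]
  out <- data.frame(query_id = colnames(q), sc, call = call,
                    check.names = FALSE, row.names = NULL)
  out
}

#' Simplex identity weights of queries over cell-type centroids
#'
#' Capybara-style identity estimate: each query rank vector `q` is
#' decomposed over the centroid matrix `C` by non-negative least squares
#' (`min ||C w - q||^2` s.t. `w >= 0`), and the weights are normalized
#' to sum to one, placing every query on the probability simplex over
#' reference cell types. The call is the argmax type when the top weight
#' reaches `hybridThreshold`; otherwise the query is called `"hybrid"`
#' and the top two types are listed — the signature of intermediate
#' identities sitting between two reference types.
#'
#' @param centroids A [CentroidSet-class].
#' @param query As in [similarityScores()].
#' @param hybridThreshold Minimum top weight for a single-type call
#'   (default 0.5).
#' @return A score table `data.frame`: `query_id`, one weight column in
#'   \[0, 1\] per type (rows sum to 1), `call`, and a logical
#'   `degenerate` column marking all-zero NNLS solutions that fell back
#'   to uniform weights.
#' @export
capybaraWeights <- function(centroids, query, hybridThreshold = 0.5) {
  q <- .asQueryMatrix(query, centroids)
  C <- exprValues(centroids)[rownames(q), , drop = FALSE]
  if (ncol(C) < 2L) stop("need at least 2 centroids")
  if (max(apply(C, 1L, function(x) diff(range(x)))) == 0)
    stop("all centroids are identical; weights are unidentifiable")
  k <- ncol(C)
  W <- matrix(0, ncol(q), k, dimnames = list(colnames(q), colnames(C)))
  degenerate <- logical(ncol(q))
  for (j in seq_len(ncol(q))) {
    w <- pracma::lsqnonneg(C, q[, j])$x
    if (sum(w) <= 0) {
      w <- rep(1 / k, k)
      degenerate[j] <- TRUE
    } else {
      w <- w / sum(w)
    }
    W[j, ] <- w
  }
  top <- max.col(W, ties.method = "first")
  call <- colnames(C)[top]
  hybrid <- W[cbind(seq_len(nrow(W)), top)] < hybridThreshold
  if (any(hybrid)) {
    second <- vapply(which(hybrid), function(i)
      order(W[i, ], decreasing = TRUE)[2L], integer(1))
    call[hybrid] <- sprintf("hybrid:%s+%s", colnames(C)[top[hybrid]],
                            colnames(C)[second])
  }
  data.frame(query_id = colnames(q), W, call = call,
             degenerate = degenerate, check.names = FALSE,
             row.names = NULL)
}

.asQueryMatrix <- function(query, centroids) {
  if (is(query, "ExpressionMatrix")) {
    if (valueKind(query) != "rank")
      query <- rankTransform(query)
    query <- exprValues(query)
  }
  if (is.null(dim(query))) {
    nm <- names(query)
    query <- matrix(query, ncol = 1L, dimnames = list(nm, "query"))
  }
  shared <- intersect(rownames(exprValues(centroids)), rownames(query))
  if (length(shared) == 0L)
    stop("query shares no genes with the centroids")
  q <- query[shared, , drop = FALSE]
  if (anyNA(q))
    stop("query rank values must be non-missing over shared genes")
  q
}

#' Rank-based differential expression between two sample groups
#'
#' Per-gene two-sided Mann-Whitney-Wilcoxon rank-sum test on the rank
#' values of two disjoint sample groups, the test used for group
#' contrasts such as in vivo versus cultured monocytes. The exact null
#' distribution is used when the smaller group has at most
#' `exactMax` samples and the gene's values are tie-free; otherwise the
#' normal approximation with tie correction (and continuity correction)
#' is used. P-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param r Rank-transformed [ExpressionMatrix-class].
#' @param annot Annotation `data.frame` covering the selected samples.
#' @param groupA,groupB Sample filters: either character vectors of
#'   sample ids, or filter strings in `"key=value,key=value"` syntax over
#'   annotation columns (see [parseGroupFilter()]), e.g.
#'   `"cell_type=monocyte,sample_source=in vivo"`.
#' @param geneStats Optional [filterGenes()] table; if given, each
#'   gene's `platform_fraction` is carried into the result so platform-
#'   driven hits can be recognized.
#' @param exactMax Largest smaller-group size for the exact path
#'   (default 8).
#' @return `data.frame`: `gene_id`, `median_a`, `median_b`,
#'   `delta_median_rank` (A minus B), `p_value`, `q_value`, and
#'   `platform_fraction` when available, sorted by p-value.
#' @export
rankSumDE <- function(r, annot, groupA, groupB, geneStats = NULL,
                      exactMax = 8L) {
  stopifnot(is(r, "ExpressionMatrix"), valueKind(r) == "rank")
  idsA <- .resolveGroup(groupA, annot, sampleIds(r))
  idsB <- .resolveGroup(groupB, annot, sampleIds(r))
  if (length(idsA) == 0L || length(idsB) == 0L)
    stop("both groups must be non-empty")
  overlap <- intersect(idsA, idsB)
  if (length(overlap))
    stop("groups overlap (", length(overlap), " shared sample(s)): ",
         paste(utils::head(overlap, 3L), collapse = ", "))
  v <- exprValues(r)
  a <- v[, idsA, drop = FALSE]
  b <- v[, idsB, drop = FALSE]
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    xa <- a[i, ][!is.na(a[i, ])]
    xb <- b[i, ][!is.na(b[i, ])]
    if (length(xa) == 0L || length(xb) == 0L)
      return(c(NA_real_, NA_real_, NA_real_))
    p <- mwwTest(xa, xb, exactMax = exactMax)
    c(stats::median(xa), stats::median(xb), p)
  }, numeric(3)))
  out <- data.frame(gene_id = rownames(v),
                    median_a = res[, 1L], median_b = res[, 2L],
                    delta_median_rank = res[, 1L] - res[, 2L],
                    p_value = res[, 3L],
                    q_value = stats::p.adjust(res[, 3L], "BH"),
                    row.names = NULL)
  if (!is.null(geneStats))
    out$platform_fraction <-
      geneStats$platform_fraction[match(out$gene_id, geneStats$gene_id)]
  out[order(out$p_value), , drop = FALSE]
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum p-value
#'
#' Exact when `min(n_a, n_b) <= exactMax` and there are no ties across
#' the pooled values; tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param xa,xb Numeric samples.
#' @param exactMax Exact-path switch point (default 8).
#' @return P-value in (0, 1\]; attribute `U` carries the statistic for
#'   group A and attribute `exact` says which path was taken.
#' @export
mwwTest <- function(xa, xb, exactMax = 8L) {
  ties <- anyDuplicated(c(xa, xb)) > 0L
  exact <- !ties && min(length(xa), length(xb)) <= exactMax
  ht <- suppressWarnings(
    stats::wilcox.test(xa, xb, exact = exact, correct = TRUE))
  structure(min(ht$p.value, 1), U = unname(ht$statistic), exact = exact)
}

#' Parse a key=value sample filter
#'
#' Mini filter syntax for selecting sample groups from an annotation
#' table: comma-separated `column=value` clauses, all of which must hold
#' (e.g. `"cell_type=monocyte,sample_source=in vivo"`).
#'
#' @param filter Filter string.
#' @param annot Annotation `data.frame`.
#' @return Character vector of matching sample ids.
#' @export
parseGroupFilter <- function(filter, annot) {
  clauses <- strsplit(filter, ",", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, nrow(annot))
  for (cl in clauses) {
    kv <- strsplit(cl, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed filter clause: '", cl, "' (expected key=value)")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(annot))
      stop("unknown annotation column in filter: ", key)
    keep <- keep & as.character(annot[[key]]) == val
  }
  annot$sample_id[keep]
}

.resolveGroup <- function(group, annot, available) {
  ids <- if (length(group) == 1L && grepl("=", group, fixed = TRUE))
    parseGroupFilter(group, annot) else as.character(group)
  ids[ids %in% available]
}
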