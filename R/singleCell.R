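#' Pseudo-bulk aggregation of single-cell counts
#'
#' Within each cluster, barcodes are shuffled with the given seed and
#' partitioned into consecutive chunks of `cellsPerSample` cells (the
#' final remainder chunk is kept, so rare clusters are always
#' represented). Each pseudo-sample is the per-gene sum of its cells'
#' raw counts — summing rather than averaging, because the subsequent
#' rank transform absorbs depth differences. Every cell is used exactly
#' once, so per-gene totals are conserved exactly. Eight-cell
#' aggregation is the default grouping used before projecting
#' single-cell data onto a bulk atlas.
#'
#' Pseudo-sample ids encode cluster, chunk size, seed and chunk index
#' (e.g. `clusterA.cs8.seed0.01`) so the composition is reproducible
#' from the id alone.
#'
#' @param counts [ExpressionMatrix-class] of kind `counts`, cells in
#'   columns.
#' @param clusters Named character vector or factor: cluster label per
#'   barcode (names are barcodes), or a `data.frame` with columns
#'   `barcode`, `cluster`. Every barcode must be labeled exactly once.
#' @param cellsPerSample Cells per pseudo-sample (default 8).
#' @param seed Integer seed for the within-cluster shuffle.
#' @return [ExpressionMatrix-class] of kind `counts`, one column per
#'   pseudo-sample, with attribute `membership` (named list mapping
#'   pseudo-sample id to its barcodes).
#' @export
aggregateCells <- function(counts, clusters, cellsPerSample = 8L, seed = 0L) {
  stopifnot(is(counts, "ExpressionMatrix"), valueKind(counts) == "counts",
            cellsPerSample >= 1L)
  cl <- .asClustering(clusters)
  barcodes <- sampleIds(counts)
  if (!setequal(barcodes, names(cl)) || anyDuplicated(names(cl)))
    stop("every barcode must carry exactly one cluster label")
  cl <- cl[barcodes]
  v <- exprValues(counts)

  membership <- list()
  cols <- list()
  for (cluster in sort(unique(cl))) {
    cells <- barcodes[cl == cluster]
    if (length(cells) == 0L) {
      warning("cluster ", cluster, " has zero cells; skipped")
      next
    }
    cells <- .seededShuffle(cells, seed, cluster)
    chunks <- split(cells, ceiling(seq_along(cells) / cellsPerSample))
    for (i in seq_along(chunks)) {
      id <- sprintf("%s.cs%d.seed%d.%02d", cluster, cellsPerSample, seed, i)
      membership[[id]] <- chunks[[i]]
      cols[[id]] <- rowSums(v[, chunks[[i]], drop = FALSE])
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(v)
  em <- ExpressionMatrix(out, "counts")
  attr(em, "membership") <- membership
  em
}

# deterministic per-cluster shuffle: one RNG stream derived from the seed
# and the cluster label, independent of cluster iteration order
.seededShuffle <- function(x, seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * 131^(seq_along(
    utf8ToInt(as.character(label))) %% 5L)) %% 1000003L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((as.integer(seed) %% 1000000L) * 1009L + as.integer(h) %% 100000L)
  x[sample.int(length(x))]
}

.asClustering <- function(clusters) {
  if (is.data.frame(clusters)) {
    if (!all(c("barcode", "cluster") %in% names(clusters)))
      stop("cluster table needs columns 'barcode' and 'cluster'")
    out <- as.character(clusters$cluster)
    names(out) <- as.character(clusters$barcode)
    return(out)
  }
  if (is.null(names(clusters)))
    stop("cluster labels must be named by barcode")
  out <- as.character(clusters)
  names(out) <- names(clusters)
  out
}

#' Project single-cell clusters onto an atlas via pseudo-bulk
#'
#' Runs [aggregateCells()] then [projectSamples()] and additionally
#' returns each cluster's centroid (mean pseudo-sample coordinates) —
#' the cluster's position on the atlas.
#'
#' @inheritParams aggregateCells
#' @param model An [AtlasModel-class].
#' @return List with `projection` (a [ProjectionResult-class] over
#'   pseudo-samples), `pseudoBulk` (the aggregated matrix), `cluster`
#'   (cluster label per pseudo-sample) and `centroids` (cluster-by-K
#'   coordinate matrix).
#' @export
projectClusters <- function(model, counts, clusters, cellsPerSample = 8L,
                            seed = 0L) {
  pb <- aggregateCells(counts, clusters, cellsPerSample, seed)
  proj <- projectSamples(model, pb)
  ids <- sampleIds(proj)
  cluster <- sub(sprintf("\\.cs%d\\.seed%d\\.\\d+$", cellsPerSample,
                         as.integer(seed)), "", ids)
  co <- atlasCoords(proj)
  centroids <- rowsum(co, cluster) / as.vector(table(cluster)[sort(unique(cluster))])
  list(projection = proj, pseudoBulk = pb, cluster = cluster,
       centroids = centroids)
}
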