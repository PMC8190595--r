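#' Fraction of a gene's rank variance attributable to platform
#'
#' Two-stage decomposition of one gene's rank values across samples.
#' Stage 1 removes cell-type structure: residuals are the ranks minus
#' their cell-type means, so genuine biology shared by samples of the
#' same cell type is not mistaken for a platform effect. Stage 2 is a
#' one-way between-platform analysis of variance on those residuals:
#' the returned fraction is `SS_between_platform / SS_total`. A gene with
#' no platform footprint scores near 0; a gene whose residuals are
#' constant within each platform but differ between platforms scores 1.
#'
#' Degenerate inputs (zero total residual variance) return 0 with
#' attribute `degenerate = TRUE`. When platform is fully confounded with
#' cell type (every cell type observed on a single platform) the fraction
#' is not interpretable and the result carries attribute
#' `confounded = TRUE` plus a warning.
#'
#' @param geneRanks Numeric vector of one gene's rank values (may contain
#'   `NA`; those samples are dropped).
#' @param platforms Platform label per sample.
#' @param cellTypes Cell-type label per sample.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' # one cell type; platforms A,A,B,B: SSB 0.16 / SST 0.2 = 0.8
#' platformVarianceFraction(c(0.2, 0.4, 0.6, 0.8),
#'                          c("A", "A", "B", "B"), rep("mono", 4))
#' @export
platformVarianceFraction <- function(geneRanks, platforms, cellTypes) {
  stopifnot(length(geneRanks) == length(platforms),
            length(geneRanks) == length(cellTypes))
  ok <- !is.na(geneRanks)
  geneRanks <- geneRanks[ok]
  platforms <- as.character(platforms)[ok]
  cellTypes <- as.character(cellTypes)[ok]
  if (length(unique(platforms)) < 2L)
    stop("platform-variance fraction undefined with a single platform")
  confounded <- all(vapply(split(platforms, cellTypes),
                           function(p) length(unique(p)) == 1L, logical(1)))
  resid <- geneRanks - stats::ave(geneRanks, cellTypes)
  sst <- sum((resid - mean(resid))^2)
  if (sst == 0) {
    out <- structure(0, degenerate = TRUE)
  } else {
    pm <- stats::ave(resid, platforms)
    ssb <- sum((pm - mean(resid))^2)
    out <- ssb / sst
  }
  if (confounded) {
    warning("platform fully confounded with cell type; ",
            "platform fraction is not interpretable")
    attr(out, "confounded") <- TRUE
  }
  out
}

#' Filter genes by platform-attributable variance and dataset coverage
#'
#' Computes the per-gene platform-variance fraction (see
#' [platformVarianceFraction()]) over all annotated samples and applies
#' the atlas gene filter: a gene is kept iff its platform fraction is at
#' most `theta` and it is measured in at least `minDatasetFrac` of the
#' contributing datasets. A gene counts as measured in a dataset iff it
#' is non-missing in at least half of that dataset's samples.
#'
#' @param r A rank-transformed [ExpressionMatrix-class].
#' @param annot Annotation `data.frame` covering every sample of `r`
#'   (see [readAnnotations()]).
#' @param theta Maximum tolerated platform-variance fraction, in (0, 1\].
#'   Default 0.25.
#' @param minDatasetFrac Minimum fraction of datasets a gene must be
#'   measured in, in (0, 1\]. Default 0.9.
#' @return A `data.frame` (one row per gene): `gene_id`,
#'   `platform_fraction` (`NA` for genes observed on fewer than two
#'   platforms; such genes are never kept), `n_datasets_measured`,
#'   `kept`. This is the
#'   per-gene "variance attributable to platform" statistic exported as
#'   `gene_stats.tsv` in atlas bundles.
#' @export
filterGenes <- function(r, annot, theta = 0.25, minDatasetFrac = 0.9) {
  stopifnot(is(r, "ExpressionMatrix"), valueKind(r) == "rank",
            theta > 0, theta <= 1,
            minDatasetFrac > 0, minDatasetFrac <= 1)
  annot <- .checkSampleCoverage(sampleIds(r), annot)
  v <- exprValues(r)
  plat <- as.character(annot$platform)
  ct <- as.character(annot$cell_type)
  ds <- as.character(annot$dataset_id)
  if (length(unique(plat)) < 2L)
    stop("gene filtering requires samples from at least 2 platforms")

  frac <- .platformFractionMatrix(v, plat, ct)

  # measured in a dataset iff non-missing in >= 50% of its samples
  nDatasets <- length(unique(ds))
  measured <- !is.na(v)
  dsLevels <- unique(ds)
  measuredIn <- vapply(dsLevels, function(d) {
    cols <- which(ds == d)
    rowMeans(measured[, cols, drop = FALSE]) >= 0.5
  }, logical(nrow(v)))
  nMeasured <- rowSums(measuredIn)

  # a gene measured on fewer than 2 platforms has an undefined fraction
  # (NA) and cannot be kept
  kept <- !is.na(frac) & frac <= theta &
    nMeasured >= minDatasetFrac * nDatasets
  if (!any(kept))
    stop("no genes pass the filter; consider relaxing theta (",
         theta, ") or minDatasetFrac (", minDatasetFrac, ")")
  data.frame(gene_id = rownames(v),
             platform_fraction = frac,
             n_datasets_measured = as.integer(nMeasured),
             kept = kept,
             row.names = NULL)
}

# vectorized two-stage decomposition over all genes; genes with missing
# values fall back to the scalar routine
.platformFractionMatrix <- function(v, plat, ct) {
  hasNA <- rowSums(is.na(v)) > 0L
  frac <- numeric(nrow(v))
  if (any(!hasNA)) {
    m <- v[!hasNA, , drop = FALSE]
    ctf <- factor(ct)
    ctMeans <- t(rowsum(t(m), ctf) / as.vector(table(ctf)))
    resid <- m - ctMeans[, as.integer(ctf), drop = FALSE]
    grand <- rowMeans(resid)
    pf <- factor(plat)
    np <- as.vector(table(pf))
    pMeans <- t(rowsum(t(resid), pf) / np)
    ssb <- rowSums(sweep(pMeans - grand, 2L, np, "*") * (pMeans - grand))
    sst <- rowSums((resid - grand)^2)
    f <- ifelse(sst == 0, 0, ssb / sst)
    frac[!hasNA] <- f
  }
  if (any(hasNA)) {
    for (i in which(hasNA))
      frac[i] <- tryCatch(
        suppressWarnings(
          as.numeric(platformVarianceFraction(v[i, ], plat, ct))),
        error = function(e) NA_real_)  # measured on < 2 platforms
  }
  frac
}
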