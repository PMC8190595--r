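#' Read a gene-by-sample expression matrix
#'
#' Dense matrices are read from TSV/CSV with the gene identifier in the
#' first column and a header row of sample identifiers. Sparse single-cell
#' matrices are read from a MatrixMarket triplet file plus companion gene
#' and barcode list files, as emitted by cell-ranger-style pipelines.
#' Duplicate gene rows (typically multiple probes per gene) are collapsed
#' by per-sample maximum; the collapse is reported in an attribute so
#' downstream manifests can record it.
#'
#' @param path Path to the matrix file (`.tsv`/`.csv`, or `.mtx` for
#'   `format = "mtx_triplet"`).
#' @param format `"tsv"`, `"csv"`, or `"mtx_triplet"`.
#' @param valueKind What the numbers are: `"counts"` or `"intensity"`.
#'   Never guessed from the file.
#' @param genesPath,barcodesPath Companion files for `mtx_triplet` (one id
#'   per line). Default to `genes.tsv` / `barcodes.tsv` next to `path`.
#' @return An [ExpressionMatrix-class]. Attribute `collapsedGenes` gives
#'   the number of duplicate gene rows collapsed (0 if none).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tf)
#' readMatrix(tf, "tsv", "counts")
#' @export
readMatrix <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                       valueKind = c("counts", "intensity"),
                       genesPath = NULL, barcodesPath = NULL) {
  format <- match.arg(format)
  valueKind <- match.arg(valueKind)
  if (!file.exists(path)) stop("matrix file not found: ", path)

  if (format == "mtx_triplet") {
    dir <- dirname(path)
    if (is.null(genesPath)) genesPath <- file.path(dir, "genes.tsv")
    if (is.null(barcodesPath)) barcodesPath <- file.path(dir, "barcodes.tsv")
    for (f in c(genesPath, barcodesPath))
      if (!file.exists(f)) stop("companion file not found: ", f)
    m <- as.matrix(Matrix::readMM(path))
    genes <- read.delim(genesPath, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    barcodes <- read.delim(barcodesPath, header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop(sprintf("MTX dimensions %dx%d do not match %d genes / %d barcodes",
                   nrow(m), ncol(m), length(genes), length(barcodes)))
    dimnames(m) <- list(genes, barcodes)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    if (length(header) < 2L)
      stop("malformed header at line 1 of ", path,
           ": expected gene id column plus at least one sample")
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
      stop("duplicate sample ids in header: ",
           paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "")
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric values in matrix body of ", path)
    rownames(m) <- genes
    colnames(m) <- sampleIds
  }

  nDup <- sum(duplicated(rownames(m)))
  if (nDup > 0L) m <- .collapseDuplicateGenes(m)
  em <- ExpressionMatrix(m, valueKind)
  attr(em, "collapsedGenes") <- nDup
  em
}

# probe-to-gene convention: duplicate gene rows collapse by per-sample max
.collapseDuplicateGenes <- function(m) {
  g <- rownames(m)
  idx <- split(seq_along(g), factor(g, levels = unique(g)))
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) return(m[i, ])
    apply(m[i, , drop = FALSE], 2L, function(col)
      if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  }, numeric(ncol(m))))
  dimnames(out) <- list(names(idx), colnames(m))
  out
}

#' Write an expression matrix as TSV
#'
#' Gene-major layout: first column `gene_id`, then one column per sample.
#' Inverse of [readMatrix()] for well-formed inputs.
#'
#' @param x An [ExpressionMatrix-class] (or plain named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path) {
  m <- if (is(x, "ExpressionMatrix")) exprValues(x) else x
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.TIERS <- c("in vivo", "ex vivo", "in vitro")

.REQUIRED_ANNOT <- c("sample_id", "dataset_id", "platform", "cell_type",
                     "sample_source", "tissue")

#' Read a sample annotation table
#'
#' Reads a TSV with one row per sample. Required columns: `sample_id`,
#' `dataset_id`, `platform`, `cell_type`, `sample_source`, `tissue`;
#' further columns (e.g. `activation_status`, `disease`,
#' `progenitor_type`) are carried through. The sample source is the
#' three-tier culture classification used throughout: `in vivo` (profiled
#' directly from tissue or blood), `ex vivo` (isolated then cultured),
#' `in vitro` (differentiated entirely in culture). Tier strings are
#' normalized case-insensitively (underscores/hyphens accepted); anything
#' outside the three tiers is an error naming the offending rows.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with canonicalized `sample_source`.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(.REQUIRED_ANNOT, names(tab))
  if (length(missing))
    stop("annotation table lacks required column(s): ",
         paste(missing, collapse = ", "))
  tab$sample_source <- normalizeTier(tab$sample_source,
                                     context = tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in annotations: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  tab
}

#' Canonicalize sample-source tier labels
#'
#' @param x Character vector of tier strings.
#' @param context Optional ids used in the error message.
#' @return Character vector drawn from `in vivo`, `ex vivo`, `in vitro`.
#' @export
normalizeTier <- function(x, context = NULL) {
  canon <- gsub("[_-]+", " ", tolower(trimws(x)))
  bad <- !canon %in% .TIERS
  if (any(bad)) {
    who <- if (is.null(context)) which(bad) else context[bad]
    stop("unknown sample_source tier(s): ",
         paste(sprintf("%s (%s)", unique(x[bad])[1L],
                       paste(utils::head(who, 5L), collapse = ", ")),
               collapse = "; "),
         " -- expected one of: ", paste(.TIERS, collapse = ", "))
  }
  canon
}

# assert every matrix sample is annotated exactly once, before any math
.checkSampleCoverage <- function(sampleIds, annot) {
  hits <- match(sampleIds, annot$sample_id)
  if (anyNA(hits))
    stop("samples missing from annotation table: ",
         paste(utils::head(sampleIds[is.na(hits)], 5L), collapse = ", "))
  annot[hits, , drop = FALSE]
}

#' Save an atlas bundle to a directory
#'
#' The bundle is a directory of plain-text files: `manifest.json` (frozen
#' config, shapes, format version), `genes.tsv`, `gene_means.tsv`,
#' `loadings.tsv`, `coords.tsv`, `samples.tsv` and `gene_stats.tsv`. All
#' matrices are gene-major and the manifest records the rank convention,
#' so a bundle is self-describing. [loadAtlas()] restores coordinates and
#' loadings bit-for-bit (values are serialized at full precision).
#'
#' @param model An [AtlasModel-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveAtlas <- function(model, dir) {
  stopifnot(is(model, "AtlasModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- ncol(model@loadings)
  manifest <- list(
    format = "rankatlas-bundle-1",
    package_version = as.character(utils::packageVersion("rankatlas")),
    n_genes = length(model@geneIds),
    n_samples = nrow(model@coords),
    K = K,
    config = model@config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(model@geneIds, file.path(dir, "genes.tsv"))
  .writeNumTable(data.frame(gene_id = model@geneIds,
                            mean_rank = unname(model@geneMeans)),
                 file.path(dir, "gene_means.tsv"))
  ld <- data.frame(gene_id = model@geneIds, model@loadings,
                   check.names = FALSE)
  colnames(ld)[-1L] <- paste0("PC", seq_len(K))
  .writeNumTable(ld, file.path(dir, "loadings.tsv"))
  co <- data.frame(sample_id = rownames(model@coords), model@coords,
                   check.names = FALSE)
  colnames(co)[-1L] <- paste0("PC", seq_len(K))
  .writeNumTable(co, file.path(dir, "coords.tsv"))
  utils::write.table(model@sampleTable, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeNumTable(model@geneStats, file.path(dir, "gene_stats.tsv"))
  .writeNumTable(data.frame(component = paste0("PC", seq_len(K)),
                            explained_variance = model@explainedVariance),
                 file.path(dir, "explained_variance.tsv"))
  invisible(dir)
}

# full-precision TSV so load(save(x)) is bit-identical
.writeNumTable <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load an atlas bundle
#'
#' Validates the bundle against its manifest (missing components and
#' shape mismatches are integrity errors) and reconstructs the
#' [AtlasModel-class].
#'
#' @param dir Bundle directory written by [saveAtlas()].
#' @return An [AtlasModel-class].
#' @export
loadAtlas <- function(dir) {
  need <- c("manifest.json", "genes.tsv", "gene_means.tsv", "loadings.tsv",
            "coords.tsv", "samples.tsv", "gene_stats.tsv",
            "explained_variance.tsv")
  have <- file.exists(file.path(dir, need))
  if (!all(have))
    stop("atlas bundle integrity error: missing ",
         paste(need[!have], collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  genes <- readLines(file.path(dir, "genes.tsv"))
  means <- read.delim(file.path(dir, "gene_means.tsv"))
  ld <- read.delim(file.path(dir, "loadings.tsv"), check.names = FALSE)
  co <- read.delim(file.path(dir, "coords.tsv"), check.names = FALSE)
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        stringsAsFactors = FALSE, quote = "")
  gs <- read.delim(file.path(dir, "gene_stats.tsv"))
  ev <- read.delim(file.path(dir, "explained_variance.tsv"))
  K <- manifest$K
  if (ncol(ld) - 1L != K || ncol(co) - 1L != K)
    stop(sprintf(paste0("atlas bundle integrity error: manifest K=%d but ",
                        "loadings have %d and coords %d component columns"),
                 K, ncol(ld) - 1L, ncol(co) - 1L))
  if (length(genes) != manifest$n_genes || nrow(ld) != manifest$n_genes)
    stop("atlas bundle integrity error: gene count mismatch with manifest")
  if (nrow(co) != manifest$n_samples)
    stop("atlas bundle integrity error: sample count mismatch with manifest")
  loadings <- as.matrix(ld[, -1L, drop = FALSE])
  rownames(loadings) <- ld$gene_id
  coords <- as.matrix(co[, -1L, drop = FALSE])
  rownames(coords) <- co$sample_id
  gm <- means$mean_rank
  names(gm) <- means$gene_id
  new("AtlasModel", geneIds = genes, geneMeans = gm[genes],
      loadings = loadings, explainedVariance = ev$explained_variance,
      coords = coords, sampleTable = samples, geneStats = gs,
      config = manifest$config)
}
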