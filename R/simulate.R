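#' Configuration for the multi-platform expression simulator
#'
#' The simulator emulates the statistical structure a cross-platform
#' atlas has to cope with — many datasets, several platforms with
#' different monotone response curves, a handful of cell types, a
#' culture (tier) effect — at desk scale, with full ground truth.
#'
#' Each gene has a baseline log-expression; each cell type adds a marker
#' effect on its own disjoint marker set. A platform distorts observed
#' values in two ways: a global monotone power response
#' `y = scale * x^exponent` (removed by ranking — this is why ranks
#' integrate platforms) and a gene-specific additive artifact of
#' magnitude `platformShift` within-type SDs (on the log scale, with a
#' random per-gene sign) on the platform-sensitive gene set, which
#' survives ranking — this is what the variance filter has to find.
#' Non-in-vivo samples additionally receive a culture shift on a
#' separate gene set, disjoint from the platform-sensitive set.
#'
#' @param nGenes Number of genes (default 2000).
#' @param nCellTypes Number of cell types (default 4).
#' @param nPlatforms Number of platforms (default 2); platform j has
#'   response exponent `platformExponents[j]`, scale
#'   `platformScales[j]`, and artifact coefficient `shiftCoefs[j]`
#'   (default an even spread over \[0, 1\], so with two platforms the
#'   second carries the full artifact).
#' @param nDatasets Number of datasets (default 4); dataset d is
#'   profiled on platform `(d - 1) %% nPlatforms + 1` and assigned tier
#'   `in vivo`/`ex vivo`/`in vitro` cyclically.
#' @param samplesPerDataset Samples per dataset (default 12), cycling
#'   over cell types.
#' @param platformSensitiveFraction Fraction `f` of genes carrying the
#'   platform artifact (default 0.1).
#' @param platformShift Artifact magnitude `delta` in within-type SD
#'   units (default 2).
#' @param cultureFraction Fraction of genes carrying the culture effect
#'   (default 0.05).
#' @param cultureShift Culture effect in SD units for ex vivo samples
#'   (default 2); in vitro samples get 1.5x this.
#' @param markerFraction Fraction of genes that are markers of each cell
#'   type (default 0.05).
#' @param markerEffect Marker log-expression effect (default 2).
#' @param sigma Within-type log-scale noise SD (default 0.5).
#' @param platformExponents,platformScales,shiftCoefs Optional explicit
#'   per-platform response curves; defaults spread exponents over
#'   \[0.7, 1.7\] and scales over \[1, 4\].
#' @param scLibSize Expected single-cell library size (default 20000).
#' @param nbDispersion Negative-binomial size parameter for single-cell
#'   counts (default 2; larger is closer to Poisson).
#' @param sfSigma Log-SD of per-cell size factors (default 0.3; 0 gives
#'   equal-depth cells).
#' @param seed Mandatory integer seed governing gene-level parameters.
#' @param noiseSeed Seed for sample-level noise (default `seed + 1`);
#'   vary it to draw new cohorts from the same simulated biology.
#' @return A validated `simConfig` list.
#' @seealso [simulateBulk()], [simulateSingleCell()]
#' @export
simConfig <- function(nGenes = 2000L, nCellTypes = 4L, nPlatforms = 2L,
                      nDatasets = 4L, samplesPerDataset = 12L,
                      platformSensitiveFraction = 0.1, platformShift = 2,
                      cultureFraction = 0.05, cultureShift = 2,
                      markerFraction = 0.05, markerEffect = 2,
                      sigma = 0.5,
                      platformExponents = NULL, platformScales = NULL,
                      shiftCoefs = NULL,
                      scLibSize = 2e4, nbDispersion = 2, sfSigma = 0.3,
                      seed, noiseSeed = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  if (nGenes < 1L || nCellTypes < 1L || nPlatforms < 1L || nDatasets < 1L)
    stop("nGenes, nCellTypes, nPlatforms and nDatasets must be positive")
  if (platformSensitiveFraction < 0 || platformSensitiveFraction >= 1)
    stop("platformSensitiveFraction must lie in [0, 1)")
  if (platformShift < 0 || cultureShift < 0 || sigma < 0)
    stop("effect magnitudes must be non-negative")
  if (is.null(platformExponents))
    platformExponents <- if (nPlatforms == 1L) 1 else
      seq(0.7, 1.7, length.out = nPlatforms)
  if (is.null(platformScales))
    platformScales <- seq(1, 4, length.out = nPlatforms)
  if (is.null(shiftCoefs))
    shiftCoefs <- if (nPlatforms == 1L) 0 else
      seq(0, 1, length.out = nPlatforms)
  stopifnot(length(platformExponents) == nPlatforms,
            length(platformScales) == nPlatforms,
            length(shiftCoefs) == nPlatforms)
  cfg <- list(nGenes = as.integer(nGenes),
              nCellTypes = as.integer(nCellTypes),
              nPlatforms = as.integer(nPlatforms),
              nDatasets = as.integer(nDatasets),
              samplesPerDataset = as.integer(samplesPerDataset),
              platformSensitiveFraction = platformSensitiveFraction,
              platformShift = platformShift,
              cultureFraction = cultureFraction,
              cultureShift = cultureShift,
              markerFraction = markerFraction,
              markerEffect = markerEffect,
              sigma = sigma,
              platformExponents = platformExponents,
              platformScales = platformScales,
              shiftCoefs = shiftCoefs,
              scLibSize = scLibSize, nbDispersion = nbDispersion,
              sfSigma = sfSigma,
              seed = as.integer(seed),
              noiseSeed = as.integer(if (is.null(noiseSeed)) seed + 1L
                                     else noiseSeed))
  class(cfg) <- "simConfig"
  cfg
}

# gene-level truth drawn only from cfg$seed: identical across cohorts that
# share the seed even when platforms/datasets/noise differ
.simGeneParams <- function(cfg) {
  set.seed(cfg$seed)
  G <- cfg$nGenes
  genes <- sprintf("gene%04d", seq_len(G))
  base <- stats::rnorm(G, mean = 3, sd = 1.5)
  perm <- sample.int(G)
  nSens <- floor(cfg$platformSensitiveFraction * G)
  nCult <- floor(cfg$cultureFraction * G)
  sensitive <- genes[perm[seq_len(nSens)]]
  culture <- genes[perm[nSens + seq_len(nCult)]]
  rest <- if (nSens + nCult > 0L) perm[-seq_len(nSens + nCult)] else perm
  nMark <- floor(cfg$markerFraction * G)
  types <- paste0("type", LETTERS[seq_len(cfg$nCellTypes)])
  markers <- list()
  offset <- 0L
  logMu <- matrix(base, G, cfg$nCellTypes,
                  dimnames = list(genes, types))
  for (t in seq_along(types)) {
    if (offset + nMark > length(rest))
      stop("not enough genes for disjoint marker sets; lower markerFraction")
    idx <- rest[offset + seq_len(nMark)]
    markers[[types[t]]] <- genes[idx]
    logMu[idx, t] <- logMu[idx, t] + cfg$markerEffect
    offset <- offset + nMark
  }
  shiftDir <- stats::setNames(sample(c(-1, 1), G, replace = TRUE), genes)
  list(genes = genes, types = types, logMu = logMu,
       sensitive = sensitive, culture = culture, markers = markers,
       shiftDir = shiftDir)
}

.TIER_COEF <- c("in vivo" = 0, "ex vivo" = 1, "in vitro" = 1.5)

#' Simulate a multi-platform, multi-dataset bulk cohort
#'
#' Draws a cohort under a [simConfig()]: a sample of type `t` in a
#' dataset on platform `p` has latent log-expression
#' `logMu[g, t] + eps`, `eps ~ N(0, sigma^2)`, plus the platform
#' artifact `dir_g * delta * sigma * shiftCoef[p]` on the
#' platform-sensitive set and the tier effect on the culture set for
#' non-in-vivo samples; the observed intensity is the monotone platform
#' response `scale_p * exp(exponent_p * latent)`. Fully deterministic
#' for a fixed config.
#'
#' @param cfg A [simConfig()].
#' @return List: `matrix` (an intensity [ExpressionMatrix-class]),
#'   `annot` (sample annotation `data.frame` in the [readAnnotations()]
#'   schema), and `truth` (list with per-sample `samples` table and the
#'   ground-truth `sensitiveGenes`, `cultureGenes`, `markerGenes`
#'   sets).
#' @export
simulateBulk <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  gp <- .simGeneParams(cfg)
  set.seed(cfg$noiseSeed)
  G <- cfg$nGenes
  tiers <- names(.TIER_COEF)
  nS <- cfg$nDatasets * cfg$samplesPerDataset
  vals <- matrix(NA_real_, G, nS)
  ids <- character(nS)
  annot <- vector("list", nS)
  sensIdx <- match(gp$sensitive, gp$genes)
  cultIdx <- match(gp$culture, gp$genes)
  s <- 0L
  for (d in seq_len(cfg$nDatasets)) {
    p <- (d - 1L) %% cfg$nPlatforms + 1L
    tier <- tiers[(d - 1L) %% length(tiers) + 1L]
    for (i in seq_len(cfg$samplesPerDataset)) {
      s <- s + 1L
      typ <- (i - 1L) %% cfg$nCellTypes + 1L
      latent <- gp$logMu[, typ] + stats::rnorm(G, 0, cfg$sigma)
      if (length(sensIdx))
        latent[sensIdx] <- latent[sensIdx] +
          gp$shiftDir[sensIdx] * cfg$platformShift * cfg$sigma *
          cfg$shiftCoefs[p]
      if (length(cultIdx))
        latent[cultIdx] <- latent[cultIdx] +
          cfg$cultureShift * cfg$sigma * .TIER_COEF[tier]
      vals[, s] <- cfg$platformScales[p] *
        exp(cfg$platformExponents[p] * latent)
      ids[s] <- sprintf("ds%02d_s%02d", d, i)
      annot[[s]] <- data.frame(
        sample_id = ids[s], dataset_id = sprintf("ds%02d", d),
        platform = sprintf("platform%d", p),
        cell_type = gp$types[typ], sample_source = tier,
        tissue = "synthetic", stringsAsFactors = FALSE)
    }
  }
  dimnames(vals) <- list(gp$genes, ids)
  annot <- do.call(rbind, annot)
  truth <- list(
    samples = data.frame(sample_id = ids,
                         true_type = annot$cell_type,
                         tier = annot$sample_source,
                         stringsAsFactors = FALSE),
    sensitiveGenes = gp$sensitive,
    cultureGenes = gp$culture,
    markerGenes = gp$markers)
  list(matrix = ExpressionMatrix(vals, "intensity"),
       annot = annot, truth = truth)
}

#' Simulate single-cell counts with cluster labels
#'
#' Counts for a cell of type `t` are negative-binomial with mean
#' `sizeFactor * libSize * mu[g, t] / sum(mu[, t])` and dispersion
#' `nbDispersion`, where `mu = exp(logMu)` shares the gene-level truth
#' of [simulateBulk()] under the same seed, and per-cell size factors
#' are log-normal. The cluster label of each cell is its true type.
#'
#' @param cfg A [simConfig()].
#' @param nCellsPerType Cells per cell type (scalar or per-type vector).
#' @return List: `counts` (counts [ExpressionMatrix-class], cells in
#'   columns), `clusters` (named cluster label per barcode), and `truth`
#'   as in [simulateBulk()].
#' @export
simulateSingleCell <- function(cfg, nCellsPerType = 100L) {
  stopifnot(inherits(cfg, "simConfig"))
  gp <- .simGeneParams(cfg)
  set.seed(cfg$noiseSeed)
  nPer <- rep_len(as.integer(nCellsPerType), cfg$nCellTypes)
  mu <- exp(gp$logMu)
  mu <- sweep(mu, 2L, colSums(mu), "/") * cfg$scLibSize
  total <- sum(nPer)
  counts <- matrix(0, cfg$nGenes, total, dimnames = list(gp$genes, NULL))
  clusters <- character(total)
  barcodes <- character(total)
  c0 <- 0L
  for (t in seq_len(cfg$nCellTypes)) {
    for (i in seq_len(nPer[t])) {
      c0 <- c0 + 1L
      sf <- if (cfg$sfSigma > 0) stats::rlnorm(1L, 0, cfg$sfSigma) else 1
      counts[, c0] <- stats::rnbinom(cfg$nGenes, mu = sf * mu[, t],
                                     size = cfg$nbDispersion)
      barcodes[c0] <- sprintf("cell_%s_%04d", gp$types[t], i)
      clusters[c0] <- gp$types[t]
    }
  }
  colnames(counts) <- barcodes
  names(clusters) <- barcodes
  truth <- list(
    samples = data.frame(sample_id = barcodes, true_type = clusters,
                         tier = "in vivo", stringsAsFactors = FALSE),
    sensitiveGenes = gp$sensitive,
    cultureGenes = gp$culture,
    markerGenes = gp$markers)
  list(counts = ExpressionMatrix(counts, "counts"),
       clusters = clusters, truth = truth)
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' @param sim Result of [simulateBulk()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrix(sim$matrix, file.path(dir, "matrix.tsv"))
  utils::write.table(sim$annot, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$sensitiveGenes,
             file.path(dir, "truth_sensitive_genes.txt"))
  writeLines(sim$truth$cultureGenes,
             file.path(dir, "truth_culture_genes.txt"))
  invisible(dir)
}
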