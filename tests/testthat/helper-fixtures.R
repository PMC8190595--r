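# small in-code fixtures shared across test files

# dense matrix with named dims
mkMatrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

# minimal annotation table for a set of sample ids
mkAnnot <- function(sampleIds, dataset = "ds1", platform = "p1",
                    cellType = "mono", tier = "in vivo",
                    tissue = "blood") {
  data.frame(sample_id = sampleIds,
             dataset_id = rep_len(dataset, length(sampleIds)),
             platform = rep_len(platform, length(sampleIds)),
             cell_type = rep_len(cellType, length(sampleIds)),
             sample_source = rep_len(tier, length(sampleIds)),
             tissue = rep_len(tissue, length(sampleIds)),
             stringsAsFactors = FALSE)
}

# write a dense TSV matrix file; returns the path
writeTsvMatrix <- function(m, path = tempfile(fileext = ".tsv"), sep = "\t") {
  header <- paste(c("gene_id", colnames(m)), collapse = sep)
  rows <- apply(m, 1L, function(x) paste(x, collapse = sep))
  writeLines(c(header, paste(rownames(m), rows, sep = sep)), path)
  path
}

# a small default cohort + atlas used by several files (built once)
.fixtureEnv <- new.env()
smallAtlasFixture <- function() {
  if (!is.null(.fixtureEnv$fx)) return(.fixtureEnv$fx)
  cfg <- simConfig(nGenes = 400L, seed = 11L)
  sim <- simulateBulk(cfg)
  r <- rankTransform(sim$matrix)
  gs <- filterGenes(r, sim$annot)
  model <- buildAtlas(r, sim$annot, gs, K = 3L)
  .fixtureEnv$fx <- list(cfg = cfg, sim = sim, r = r, gs = gs, model = model)
  .fixtureEnv$fx
}

# naive O(n^2) percentile rank: for each value, count pairwise wins plus
# half-ties -- independent of the rank() path used by the package
naiveRank <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  for (i in which(ok)) {
    wins <- sum(x[ok] < x[i])
    ties <- sum(x[ok] == x[i])  # includes self
    out[i] <- ((wins + (ties + 1) / 2) - 0.5) / n
  }
  out
}

# brute-force two-sided MWW p by full enumeration of label assignments
enumMwwP <- function(xa, xb) {
  pool <- c(xa, xb)
  na <- length(xa)
  U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- abs(U(xa, xb) - na * length(xb) / 2)
  combs <- utils::combn(length(pool), na)
  stat <- apply(combs, 2L, function(idx)
    abs(U(pool[idx], pool[-idx]) - na * length(pool[-idx]) / 2))
  mean(stat >= obs - 1e-12)
}
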