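---
title: "Rank-based cross-platform atlases: models, parameters and design choices"
author: "rankatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based cross-platform atlases: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankatlas)
```

## The problem

A reference transcriptome atlas for a cell lineage — say, human myeloid
cells — has to pool samples profiled over a decade on different
microarray generations, bulk RNA-seq and single-cell RNA-seq. Absolute
expression values are not comparable across these platforms: response
curves differ in scale and shape, probe affinities are platform-specific,
and sequencing depth varies by orders of magnitude. At the same time,
the most interesting questions the atlas answers are *comparative*:
does a stem-cell-derived macrophage resemble a tissue-resident one;
does culturing a monocyte move it toward a tissue phenotype? This
vignette explains how `rankatlas` addresses this, what every tunable
parameter means, and why each numerical choice was made.

## Percentile-rank integration

Each sample is reduced to within-sample percentile ranks across its
measured genes: `r = (rank - 0.5) / n`, ties averaged. The convention
is chosen over the alternatives (`rank/n`, `(rank-1)/(n-1)`) because it
is symmetric around 0.5, maps a constant sample to exactly 0.5, and is
free of the gene-panel size, so a 20,000-gene RNA-seq sample and a
12,000-probe array land on the same scale. Ranks are invariant to any
strictly increasing per-sample transform — the entire family of
normalizations (CPM, TPM, quantile scaling, log) and any monotone
platform response collapse to the same vector. The cost is that
magnitude information within a sample is discarded; the atlas trades it
for comparability.

Ranking is always computed over a sample's **full measured gene set**,
never after subsetting to atlas genes. Re-ranking after subsetting
would make a query's coordinates depend discontinuously on the atlas
gene list, and two queries with different missingness patterns would be
ranked on different scales. Missing values are an explicit mask: they
are excluded from `n` for that sample and stay missing downstream.

## Platform-variance gene filtering

Monotone distortions vanish under ranking, but gene-specific artifacts
(probe cross-hybridization, 3'-bias, GC effects) do not: they move a
gene's rank on one platform relative to another. For each gene we
compute the fraction of rank variance attributable to platform in two
stages:

1. residuals = rank values minus their **cell-type means**. Without
   this adjustment a cell type profiled predominantly on one platform
   would inflate the platform sum of squares with genuine biology. The
   stratification is a modelling choice of this package, recorded in
   the atlas manifest.
2. fraction = between-platform sum of squares of those residuals over
   their total sum of squares (one-way ANOVA R²). Zero total variance
   returns 0 with a degeneracy flag; platform fully confounded with
   cell type yields a warning, since the fraction is then
   uninterpretable.

A gene is retained iff its fraction is ≤ `theta` **and** it is measured
(non-missing in ≥ 50% of a dataset's samples) in ≥ `minDatasetFrac` of
datasets. Defaults `theta = 0.25` and `minDatasetFrac = 0.9` enforce
aggressive platform cleanup and near-universal coverage; both are
exposed in the API and the CLI, and both are frozen into the bundle
manifest. A gene observed on fewer than two platforms has an undefined
fraction (`NA`) and is never retained.

## The PCA frame and projection semantics

The retained genes' rank profiles are centred at their per-gene mean
`mu` and decomposed by SVD; the first `K` loadings (default `K = 3`,
matching the 2D/3D displays such atlases are browsed in) and `mu` are
frozen. Loading signs are fixed by making each component's
largest-magnitude entry positive, so rebuilding the same atlas is
bit-identical — useful for regression-testing bundles.

Projection maps a query as `t(L) %*% (r - mu)`. Three deliberate
semantics:

* **No re-centring on the query.** Queries are benchmarked against a
  frozen frame; co-embedding (refitting on reference + query) would let
  a large query cohort bend the atlas toward itself.
* **Mean imputation** for atlas genes missing from the query: imputed
  genes contribute exactly zero after centring, biasing the query
  toward the atlas origin rather than in an arbitrary direction. The
  per-query coverage is always reported, and coverage below 0.5
  warns; the alternative (dropping genes and refitting loadings per
  query) would place different queries in different frames.
* Each reference sample counts once; datasets are not re-weighted by
  size. The alternative (weighting samples so each dataset contributes
  equally) is defensible but changes the frame; we document rather than
  switch.

## Identity scoring

Centroids are per-type mean rank vectors over atlas genes,
reconstructed from the stored K-component representation (clipped to
[0, 1] where truncation overshoots). Types with fewer than three
reference samples are flagged low-confidence rather than dropped.

*Correlation mode* reports the Pearson correlation between query and
centroid **deviations from the average reference profile** (the
per-gene mean across centroids). Correlating raw rank vectors would
push every score toward one, because all cell types share the dominant
housekeeping-expression component; removing the shared profile makes
the score discriminative, and gives the clean identities: query =
centroid scores 1, mirror-image deviations score −1.

*Weight mode* solves non-negative least squares `min ||Cw - q||²`,
`w ≥ 0` (Lawson–Hanson, via `pracma::lsqnonneg`) and normalizes `w` to
the probability simplex. An all-zero solution falls back to uniform
weights with a degeneracy flag. The call is the argmax type when the
top weight reaches 0.5; otherwise the query is called a hybrid of its
top two types. The 0.5 threshold is a package default (configurable),
chosen so a call requires a strict majority of identity mass —
intermediate populations sitting between two reference types are
exactly the case the hybrid call is meant to surface.

## Differential rank expression

Group contrasts use the two-sided Mann–Whitney–Wilcoxon test on rank
values per gene. The exact null distribution is used when the smaller
group has ≤ 8 samples and the pooled values are tie-free — below that
size the normal approximation is visibly granular, and exactness is
cheap; above it, or with ties, the tie-corrected normal approximation
with continuity correction is used. P-values are Benjamini–Hochberg
adjusted across genes, and each gene's platform-variance fraction can
be carried into the table so platform-driven hits are recognizable.
Group filters use a small `column=value,column=value` syntax over the
annotation table.

## Pseudo-bulk aggregation

Single-cell clusters are projected after aggregating cells into
pseudo-bulk samples: within each cluster, barcodes are shuffled with a
caller-supplied seed and cut into consecutive chunks of
`cellsPerSample` (default 8) cells whose raw counts are summed. Design
choices: the final remainder chunk is **kept**, so rare clusters are
always represented (at the price of noisier trailing pseudo-samples,
whose size is recoverable from the membership attribute); counts are
**summed, not averaged**, because the subsequent rank transform absorbs
depth; grouping is random rather than expression-guided, with the seed,
chunk size and chunk index encoded in each pseudo-sample id so any
composition is reproducible from its name. Conservation is exact: each
cell is used once, and per-gene totals over pseudo-samples equal totals
over cells.

## The synthetic cohort generator

The simulator generates the statistical structure the method assumes,
not myeloid biology: no real marker genes, no specific subsets. A gene
has a baseline log-expression `N(3, 1.5²)`; each of `nCellTypes`
(default 4) types adds a `markerEffect = 2` log-effect on its own
disjoint 5% marker set; within-type noise is log-normal with
`sigma = 0.5`. Platforms distort doubly: a monotone power response
`y = scale · x^exponent` (exponents spread over 0.7–1.7), which ranking
must and does remove, and an additive log-scale artifact of
`platformShift = 2` within-type SDs, with random per-gene sign, on a
`platformSensitiveFraction = 0.1` gene set — which survives ranking and
is precisely what the filter must find. This pairing is what makes the
filter's task non-trivial: a simulator with only monotone distortion
would be solved by ranking alone. Non-in-vivo samples get an additional
culture shift on a separate, disjoint 5% gene set (ex vivo coefficient
1, in vitro 1.5), giving the tier-separation signal along atlas axes.
The default cohort — 4 datasets × 12 samples on 2 platforms, 2000
genes — runs in seconds and is the size used throughout the tests and
the acceptance script; gene-level truth depends only on `seed`, so
held-out cohorts (new platforms, new noise via `noiseSeed`) share the
same biology by construction.

What the simulator does **not** emulate — correlated gene modules,
compositional tissue effects, dropout structure beyond the negative
binomial, annotation errors — bounds what passing tests show: they
validate the machinery under the model's own assumptions, not
performance on any particular real cohort.

## Numerical notes and limitations

* PCA is dense `svd()` on the centred rank matrix; at atlas scale
  (thousands of genes, hundreds of samples) this is well within a
  second. `K` above the matrix rank is refused with the achievable
  rank.
* Bundle serialization writes doubles with 17 significant digits, so
  `loadAtlas(saveAtlas(m))` reproduces loadings and coordinates
  bit-for-bit; manifests record shapes and the rank convention, and
  loading verifies both.
* Duplicate gene rows (multi-probe genes) collapse by per-sample
  maximum — the common probe-to-gene convention; under ranking the
  alternative (mean) differs only when probes disagree, and the chosen
  policy is recorded in the manifest.
* The exact MWW path enumerates via the null distribution of U and is
  only used for tie-free small groups; rank data are tie-prone, so the
  tie-corrected approximation is the common path in practice.
* Gene matching is by exact identifier string; the package is
  namespace-agnostic (Ensembl IDs recommended) and performs no probe
  annotation or ortholog mapping.
* The platform-variance filter assumes every cell type appears on more
  than one platform somewhere in the compendium; fully confounded
  designs are flagged, not fixed.
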