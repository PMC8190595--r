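#' rankatlas: cross-platform transcriptome reference atlases
#'
#' Integrates heterogeneous expression datasets (microarray, bulk
#' RNA-seq, pseudo-bulked single-cell) into a common reference atlas.
#' The pipeline is: per-sample percentile-rank transformation
#' ([rankTransform()]); removal of genes whose rank variance is
#' dominated by profiling platform ([filterGenes()]); a frozen PCA
#' coordinate frame over the retained genes ([buildAtlas()]);
#' projection of external bulk ([projectSamples()]) or single-cell
#' ([aggregateCells()], [projectClusters()]) samples into that frame;
#' and annotation against reference cell types by correlation
#' ([similarityScores()]) or simplex identity weights
#' ([capybaraWeights()]), with rank-based differential expression
#' ([rankSumDE()]). A seeded simulator with ground truth
#' ([simulateBulk()], [simulateSingleCell()]) supports validation.
#'
#' A command-line interface over these functions is installed at
#' `system.file("scripts", "atlas.R", package = "rankatlas")`.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rnbinom rlnorm
NULL
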