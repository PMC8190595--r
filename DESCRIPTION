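Package: rankatlas
Title: Cross-Platform Transcriptome Reference Atlases via Percentile-Rank
    Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs integrated reference atlases from heterogeneous
    gene-expression datasets (microarray, bulk RNA-seq and pseudo-bulked
    single-cell data). Samples are placed on a common scale by a per-sample
    percentile-rank transformation; genes whose rank variance is dominated
    by profiling platform are removed by a cell-type-adjusted variance
    decomposition; the retained genes define a frozen PCA coordinate frame.
    External bulk or single-cell samples can be projected into that frame
    and annotated against reference cell types by correlation similarity or
    by non-negative simplex identity weights, with rank-based differential
    expression between annotated groups. A seeded multi-platform simulator
    with ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'io.R'
    'rank.R'
    'platform.R'
    'atlas.R'
    'singleCell.R'
    'annotate.R'
    'simulate.R'
    'zzz.R'
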