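test_that("two centered samples land at equal-magnitude opposite coordinates", {
  v <- mkMatrix(matrix(c(1, 2, 3, 3, 2, 1), 3, 2))
  r <- rankTransform(ExpressionMatrix(v, "counts"))
  annot <- mkAnnot(colnames(v))
  gs <- data.frame(gene_id = rownames(v), platform_fraction = 0,
                   n_datasets_measured = 1L, kept = TRUE)
  model <- buildAtlas(r, annot, gs, K = 1L)
  co <- atlasCoords(model)
  expect_equal(co[1, 1], -co[2, 1])
  expect_gt(abs(co[1, 1]), 0)
})

test_that("loadings are orthonormal and explained variance is coherent", {
  fx <- smallAtlasFixture()
  L <- atlasLoadings(fx$model)
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  ev <- explainedVariance(fx$model)
  expect_true(all(diff(ev) <= 1e-12))
  # per-component variance of coordinates equals the stored eigenvalue
  co <- atlasCoords(fx$model)
  expect_equal(unname(apply(co, 2, var)), unname(ev), tolerance = 1e-8)
})

test_that("deterministic sign convention makes rebuilds bit-comparable", {
  fx <- smallAtlasFixture()
  again <- buildAtlas(fx$r, fx$sim$annot, fx$gs, K = 3L)
  expect_identical(atlasLoadings(again), atlasLoadings(fx$model))
  expect_identical(atlasCoords(again), atlasCoords(fx$model))
  for (k in 1:3) {
    L <- atlasLoadings(fx$model)
    expect_gt(L[which.max(abs(L[, k])), k], 0)
  }
})

test_that("cell types separate along the leading axis on synthetic data", {
  fx <- smallAtlasFixture()
  co <- atlasCoords(fx$model)
  ct <- sampleTable(fx$model)$cell_type
  # direct variance decomposition of PC1 coordinates by type
  grand <- mean(co[, 1])
  between <- sum(tapply(co[, 1], ct, function(x)
    length(x) * (mean(x) - grand)^2)) / (length(unique(ct)) - 1)
  within <- sum(tapply(co[, 1], ct, function(x)
    sum((x - mean(x))^2))) / (length(ct) - length(unique(ct)))
  expect_gt(between / within, 1)
})

test_that("K beyond the matrix rank is refused with the achievable K", {
  set.seed(33)
  v <- matrix(rpois(20, 20), 5, 4)
  v[, 4] <- v[, 3]  # duplicated sample: centered rank drops to 2
  v <- mkMatrix(v)
  r <- rankTransform(ExpressionMatrix(v, "counts"))
  gs <- data.frame(gene_id = rownames(v), platform_fraction = 0,
                   n_datasets_measured = 1L, kept = TRUE)
  expect_error(buildAtlas(r, mkAnnot(colnames(v)), gs, K = 3L),
               "achievable K is 2")
})

test_that("training samples re-project onto their stored coordinates", {
  fx <- smallAtlasFixture()
  proj <- projectSamples(fx$model, fx$sim$matrix)
  expect_lt(max(abs(atlasCoords(proj) - atlasCoords(fx$model))), 1e-8)
  expect_equal(geneCoverage(proj), rep(1, ncol(exprValues(fx$r))))
})

test_that("projection is invariant to monotone transforms of the query", {
  fx <- smallAtlasFixture()
  q <- exprValues(fx$sim$matrix)[, 1:5]
  p1 <- projectSamples(fx$model, ExpressionMatrix(q, "intensity"))
  p2 <- projectSamples(fx$model, ExpressionMatrix(log1p(q), "intensity"))
  expect_identical(atlasCoords(p1), atlasCoords(p2))
})

test_that("a query at the atlas mean maps to the origin; missing genes are
           mean-imputed and counted against coverage", {
  fx <- smallAtlasFixture()
  mu <- fx$model@geneMeans
  muQuery <- matrix(mu, ncol = 1, dimnames = list(names(mu), "q"))
  pr <- projectSamples(fx$model, ExpressionMatrix(muQuery, "rank"))
  expect_lt(max(abs(atlasCoords(pr))), 1e-10)

  # drop 40% of atlas genes from a query
  keep <- names(mu)[seq_len(ceiling(0.6 * length(mu)))]
  q <- exprValues(fx$sim$matrix)[keep, 1:2]
  expect_warning(pr2 <- projectSamples(fx$model,
                                       ExpressionMatrix(q, "intensity")),
                 NA)
  expect_equal(unname(geneCoverage(pr2)),
               rep(length(keep) / length(mu), 2), tolerance = 1e-12)

  few <- exprValues(fx$sim$matrix)[names(mu)[1:40], 1, drop = FALSE]
  expect_warning(projectSamples(fx$model, ExpressionMatrix(few, "intensity")),
                 "covers only")
  noGenes <- mkMatrix(matrix(1:4, 2, 2), genes = c("zz1", "zz2"))
  expect_error(projectSamples(fx$model, ExpressionMatrix(noGenes, "counts")),
               "no gene identifiers")
})

test_that("axis summaries expose tier separation with a rank-sum p-value", {
  # two cell types so a principal axis is free to pick up the tier shift
  cfg <- simConfig(nGenes = 500L, nCellTypes = 2L, nDatasets = 6L, seed = 5L)
  sim <- simulateBulk(cfg)
  keep <- sim$annot$sample_source %in% c("in vivo", "ex vivo")
  v <- exprValues(sim$matrix)[, keep]
  annot <- sim$annot[keep, ]
  r <- rankTransform(ExpressionMatrix(v, "intensity"))
  gs <- filterGenes(r, annot)
  model <- buildAtlas(r, annot, gs, K = 3L)
  ps <- vapply(1:3, function(k)
    attr(axisSummary(model, k, "sample_source"), "rank_sum_p"), numeric(1))
  expect_lt(min(ps), 0.01)  # some axis captures the culture shift
  sm <- axisSummary(model, 1L, "cell_type")
  expect_setequal(sm$group, unique(annot$cell_type))
  expect_true(all(c("median", "q25", "q75") %in% names(sm)))
  expect_error(axisSummary(model, 1L, "nope"), "unknown annotation")
  expect_error(axisSummary(model, 9L), "between 1 and K")
})
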