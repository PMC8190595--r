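test_that("centroids are per-type means of reference rank profiles", {
  fx <- smallAtlasFixture()
  cen <- buildCentroids(fx$model)
  expect_s4_class(cen, "CentroidSet")
  expect_setequal(cellTypes(cen), unique(fx$sim$annot$cell_type))
  # hand-recompute one centroid from the K-dim reconstruction
  model <- fx$model
  ranks <- model@geneMeans + atlasLoadings(model) %*% t(atlasCoords(model))
  isA <- sampleTable(model)$cell_type == "typeA"
  expect_equal(unname(exprValues(cen)[, "typeA"]),
               unname(pmin(pmax(rowMeans(ranks[, isA]), 0), 1)),
               tolerance = 1e-12)
  # each centroid is on average closest to its own type's samples
  d <- as.matrix(dist(t(cbind(exprValues(cen), ranks))))
  k <- ncol(exprValues(cen))
  for (t in cellTypes(cen)) {
    dt <- d[t, -(1:k)]
    own <- mean(dt[sampleTable(model)$cell_type == t])
    other <- mean(dt[sampleTable(model)$cell_type != t])
    expect_lt(own, other)
  }
  expect_error(buildCentroids(fx$model, by = "absent"), "unknown")
})

test_that("correlation similarity matches the closed-form Pearson formula", {
  fx <- smallAtlasFixture()
  cen <- buildCentroids(fx$model)
  C <- exprValues(cen)
  # self-similarity: a query equal to a centroid scores exactly 1 there
  sc <- similarityScores(cen, C[, "typeB"])
  expect_equal(sc$typeB, 1)
  expect_identical(sc$call, "typeB")
  # reflected deviations anti-correlate
  mu <- rowMeans(C)
  refl <- mu + (mu - C[, "typeC"])
  expect_equal(similarityScores(cen, refl)$typeC, -1)
  # random queries against the hand formula cov/(sd*sd) on deviations
  # from the average reference profile
  set.seed(14)
  q <- matrix(runif(nrow(C) * 3), ncol = 3,
              dimnames = list(rownames(C), paste0("q", 1:3)))
  sc2 <- similarityScores(cen, q)
  for (j in 1:3) for (t in colnames(C)) {
    a <- q[, j] - mu; b <- C[, t] - mu
    hand <- mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
    expect_equal(sc2[[t]][j], hand, tolerance = 1e-12)
  }
  expect_error(similarityScores(cen, setNames(rep(0.5, nrow(C)),
                                              rownames(C))),
               "zero-variance")
})

test_that("simplex weights recover pure and mixed identities", {
  fx <- smallAtlasFixture()
  cen <- buildCentroids(fx$model)
  C <- exprValues(cen)
  wPure <- capybaraWeights(cen, C[, "typeD"])
  expect_equal(wPure$typeD, 1, tolerance = 1e-6)
  expect_identical(wPure$call, "typeD")

  mix <- 0.6 * C[, 1] + 0.4 * C[, 2]
  names(mix) <- rownames(C)
  wMix <- capybaraWeights(cen, mix)
  expect_equal(wMix[[colnames(C)[1]]], 0.6, tolerance = 0.01)
  expect_equal(wMix[[colnames(C)[2]]], 0.4, tolerance = 0.01)
  expect_identical(wMix$call, colnames(C)[1])

  # a three-way mixture with no dominant component is called hybrid,
  # listing the top two types
  mix3 <- 0.4 * C[, 1] + 0.35 * C[, 2] + 0.25 * C[, 3]
  names(mix3) <- rownames(C)
  wMix3 <- capybaraWeights(cen, mix3)
  expect_match(wMix3$call,
               sprintf("^hybrid:%s\\+%s$", colnames(C)[1], colnames(C)[2]))

  # dense grid-search oracle over the 2-simplex spanned by c1, c2
  grid <- seq(0, 1, by = 0.001)
  sse <- vapply(grid, function(a)
    sum((a * C[, 1] + (1 - a) * C[, 2] - mix)^2), numeric(1))
  expect_equal(grid[which.min(sse)], 0.6, tolerance = 0.005)
})

test_that("weights always lie on the probability simplex", {
  fx <- smallAtlasFixture()
  cen <- buildCentroids(fx$model)
  set.seed(15)
  q <- matrix(runif(nrow(exprValues(cen)) * 20), ncol = 20,
              dimnames = list(geneIds(cen), paste0("q", 1:20)))
  w <- capybaraWeights(cen, q)
  W <- as.matrix(w[, cellTypes(cen)])
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-8))
})

test_that("held-out samples from an unseen platform are classified correctly", {
  fx <- smallAtlasFixture()
  cen <- buildCentroids(fx$model)
  cfgHo <- simConfig(nGenes = 400L, seed = 11L, noiseSeed = 1234L,
                     nPlatforms = 3L, nDatasets = 3L,
                     platformExponents = c(0.7, 1.2, 2.1),
                     platformScales = c(1, 2, 0.5),
                     shiftCoefs = c(0, 0.5, 1))
  simHo <- simulateBulk(cfgHo)
  unseen <- simHo$annot$platform == "platform3"
  r <- rankTransform(ExpressionMatrix(
    exprValues(simHo$matrix)[, unseen], "intensity"))
  w <- capybaraWeights(cen, exprValues(r))
  truth <- simHo$truth$samples$true_type[unseen]
  expect_gte(mean(w$call == truth), 0.95)
})

test_that("the worked rank-sum case and group symmetry hold", {
  p <- mwwTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(as.numeric(p), 0.1)
  expect_equal(attr(p, "U"), 0)
  expect_true(attr(p, "exact"))

  pSame <- mwwTest(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_equal(as.numeric(pSame), 1)

  fx <- smallAtlasFixture()
  a <- "cell_type=typeA,sample_source=in vivo"
  b <- "cell_type=typeA,sample_source=ex vivo"
  de1 <- rankSumDE(fx$r, fx$sim$annot, a, b, geneStats = fx$gs)
  de2 <- rankSumDE(fx$r, fx$sim$annot, b, a)
  m <- match(de1$gene_id, de2$gene_id)
  expect_equal(de1$delta_median_rank, -de2$delta_median_rank[m])
  expect_equal(de1$p_value, de2$p_value[m])
  expect_true(all(de1$p_value > 0 & de1$p_value <= 1))
  expect_true(all(de1$q_value > 0 & de1$q_value <= 1))
  expect_true("platform_fraction" %in% names(de1))
  # a tier-wide fresh-vs-cultured contrast: culture-shifted genes are the
  # hits, everything else mostly is not
  deTier <- rankSumDE(fx$r, fx$sim$annot, "sample_source=in vivo",
                      "sample_source=ex vivo")
  isCult <- deTier$gene_id %in% fx$sim$truth$cultureGenes
  expect_gt(mean(deTier$q_value[isCult] <= 0.05), 0.8)
  expect_lt(mean(deTier$q_value[!isCult] <= 0.05), 0.2)
})

test_that("exact-path p-values equal full enumeration on random small cases", {
  set.seed(16)
  for (i in 1:200) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    x <- sample(100, na + nb)  # tie-free
    p <- mwwTest(x[1:na], x[-(1:na)])
    expect_true(attr(p, "exact"))
    expect_equal(as.numeric(p), enumMwwP(x[1:na], x[-(1:na)]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment has the step-up property versus a hand version", {
  set.seed(17)
  p <- runif(60)^2
  handBH <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(q, 1); out
  }
  expect_equal(p.adjust(p, "BH"), handBH(p))
  q <- handBH(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("group filters resolve and invalid group pairs are refused", {
  fx <- smallAtlasFixture()
  ids <- parseGroupFilter("cell_type=typeA,sample_source=in vivo",
                          fx$sim$annot)
  expect_true(all(fx$sim$annot$cell_type[match(ids, fx$sim$annot$sample_id)]
                  == "typeA"))
  expect_error(parseGroupFilter("nope=1", fx$sim$annot), "unknown annotation")
  expect_error(parseGroupFilter("malformed", fx$sim$annot), "key=value")
  expect_error(rankSumDE(fx$r, fx$sim$annot, "cell_type=typeA",
                         "cell_type=typeA"), "overlap")
  expect_error(rankSumDE(fx$r, fx$sim$annot, "cell_type=typeA",
                         "cell_type=nonexistent"), "non-empty")
})
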