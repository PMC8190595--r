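test_that("platform fraction matches the hand-computed one-way ANOVA", {
  # one cell type; A: 0.2, 0.4 vs B: 0.6, 0.8; residual platform means
  # -0.2 / +0.2 about a zero grand mean: SSB 0.16, SST 0.2 -> 0.8
  f <- platformVarianceFraction(c(0.2, 0.4, 0.6, 0.8),
                                c("A", "A", "B", "B"), rep("mono", 4))
  expect_equal(as.numeric(f), 0.8, tolerance = 1e-12)
})

test_that("degenerate and balanced cases hit the documented edges", {
  f0 <- platformVarianceFraction(rep(0.4, 6), rep(c("A", "B"), 3),
                                 rep("mono", 6))
  expect_equal(as.numeric(f0), 0)
  expect_true(isTRUE(attr(f0, "degenerate")))

  # equal per-platform means -> no between-platform SS
  fEq <- platformVarianceFraction(c(0.1, 0.9, 0.2, 0.8),
                                  c("A", "A", "B", "B"), rep("m", 4))
  expect_equal(as.numeric(fEq), 0)

  expect_error(platformVarianceFraction(c(0.1, 0.2), c("A", "A"),
                                        c("m", "m")), "single platform")
  expect_warning(
    platformVarianceFraction(c(0.1, 0.2, 0.8, 0.9), c("A", "A", "B", "B"),
                             c("m1", "m1", "m2", "m2")), "confounded")
})

test_that("cell-type adjustment keeps shared biology out of the fraction", {
  # two cell types with a large type effect, platform effect absent:
  # unadjusted between-platform SS would be inflated by the type imbalance
  ranks <- c(0.9, 0.85, 0.1, 0.15, 0.9, 0.88, 0.12, 0.1)
  ct <- rep(c("hi", "hi", "lo", "lo"), 2)
  plat <- rep(c("A", "B"), each = 4)
  f <- platformVarianceFraction(ranks, plat, ct)
  expect_lt(as.numeric(f), 0.1)
})

test_that("fraction is always in [0, 1] and 1 only for pure platform shifts", {
  set.seed(3)
  for (i in 1:50) {
    n <- 12
    plat <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(plat)) < 2) next
    ct <- sample(c("x", "y"), n, replace = TRUE)
    f <- suppressWarnings(as.numeric(
      platformVarianceFraction(runif(n), plat, ct)))
    expect_gte(f, 0); expect_lte(f, 1)
  }
  # residuals constant within platform, different between -> exactly 1
  f1 <- platformVarianceFraction(c(0.2, 0.2, 0.7, 0.7),
                                 c("A", "A", "B", "B"), rep("m", 4))
  expect_equal(as.numeric(f1), 1)
})

test_that("vectorized per-gene fractions equal the scalar routine", {
  fx <- smallAtlasFixture()
  v <- exprValues(fx$r)
  annot <- fx$sim$annot
  idx <- seq(1, nrow(v), by = 37)
  for (i in idx) {
    f <- suppressWarnings(as.numeric(platformVarianceFraction(
      v[i, ], annot$platform, annot$cell_type)))
    expect_equal(fx$gs$platform_fraction[i], f, tolerance = 1e-12)
  }
})

test_that("gene filter applies both the theta and the coverage rule", {
  # 4 datasets on 2 platforms; one gene jumps across the filler band on
  # platform B only, one gene is missing from 3 of 4 datasets, and a
  # band of well-separated filler genes is platform-stable
  set.seed(19)
  nS <- 16
  plat <- rep(c("pA", "pB", "pA", "pB"), each = 4)
  filler <- exp(matrix(rep(seq(log(10), log(100), length.out = 18), nS),
                       18, nS) + matrix(rnorm(18 * nS, 0, 0.3), 18, nS))
  shifted <- ifelse(plat == "pB", 500, 1)   # bottom on pA, top on pB
  sparse <- c(runif(4, 50, 60), rep(NA, 12))
  v <- mkMatrix(rbind(shifted, filler, sparse),
                genes = c("shifted", sprintf("f%02d", 1:18), "sparse"),
                samples = sprintf("s%d", 1:nS))
  annot <- mkAnnot(colnames(v),
                   dataset = rep(c("d1", "d2", "d3", "d4"), each = 4),
                   platform = plat)
  r <- rankTransform(ExpressionMatrix(v, "intensity"))
  gs <- filterGenes(r, annot, theta = 0.25, minDatasetFrac = 0.9)
  expect_false(gs$kept[gs$gene_id == "shifted"])
  expect_gt(gs$platform_fraction[gs$gene_id == "shifted"], 0.25)
  expect_gt(mean(gs$kept[startsWith(gs$gene_id, "f")]), 0.8)
  expect_false(gs$kept[gs$gene_id == "sparse"])
  expect_identical(gs$n_datasets_measured[gs$gene_id == "sparse"], 1L)
  # observed on a single platform only: fraction undefined
  expect_true(is.na(gs$platform_fraction[gs$gene_id == "sparse"]))

  expect_error(filterGenes(r, annot, theta = 1e-9, minDatasetFrac = 1),
               "no genes pass")
})

test_that("computed platform fraction grows with the injected shift", {
  # seeded monotonicity: larger additive platform shift on one gene never
  # lowers its platform fraction
  set.seed(21)
  base <- rnorm(24)
  plat <- rep(c("A", "B"), each = 12)
  ct <- rep(rep(c("x", "y"), each = 6), 2)
  prev <- -Inf
  for (delta in c(0, 0.5, 1, 2, 4)) {
    x <- base + delta * (plat == "B")
    v <- mkMatrix(rbind(exp(x), matrix(exp(rnorm(24 * 20)), 20, 24)),
                  genes = c("target", sprintf("g%d", 1:20)),
                  samples = sprintf("s%d", 1:24))
    r <- rankTransform(ExpressionMatrix(v, "intensity"))
    f <- suppressWarnings(as.numeric(platformVarianceFraction(
      exprValues(r)["target", ], plat, ct)))
    expect_gte(f, prev - 1e-12)
    prev <- f
  }
})
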