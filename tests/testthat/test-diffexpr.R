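test_that("quantile normalisation equalises column distributions", {
  # already-identical columns are untouched
  m <- matrix(rep(c(1, 5, 9), 3), nrow = 3)
  expect_equal(quantileNormalize(m), m)

  # 2 genes x 2 samples worked example: columns (1,2) and (3,4) both
  # become the mean order statistics (1.5, 3.5)
  m2 <- matrix(c(1, 3, 2, 4), ncol = 2)
  out <- quantileNormalize(m2)
  expect_equal(sort(out[, 1]), c(1.5, 3.5))
  expect_equal(sort(out[, 2]), c(1.5, 3.5))
  # rank order preserved within columns
  expect_equal(order(out[, 1]), order(m2[, 1]))

  # property: identical sorted values in every column afterwards
  set.seed(1)
  r <- matrix(rnorm(200), 50, 4)
  qn <- quantileNormalize(r)
  ref <- sort(qn[, 1])
  for (j in 2:4) expect_equal(sort(qn[, j]), ref)

  expect_identical(quantileNormalize(r[, 1, drop = FALSE]),
                   r[, 1, drop = FALSE])
  expect_error(quantileNormalize(matrix(c(1, NA), 1)), "missing")
})

test_that("variance prior: degenerate guards and parameter recovery", {
  expect_identical(estimatePrior(rep(2.5, 100), df = 6),
                   list(d0 = Inf, s02 = 2.5))
  expect_identical(estimatePrior(c(1, 2), df = 6)$d0, Inf)
  expect_error(estimatePrior(rep(0, 50), df = 6), "zero")

  set.seed(33)
  d0 <- 4; s02 <- 1; df <- 6
  sigma2 <- s02 * d0 / rchisq(1e4, d0)
  s2 <- sigma2 * rchisq(1e4, df) / df
  pr <- estimatePrior(s2, df)
  expect_gt(pr$d0, 2.5); expect_lt(pr$d0, 6)
  expect_gt(pr$s02, 0.8); expect_lt(pr$s02, 1.25)

  # independent cross-check against the established empirical-Bayes fit
  fl <- limma::fitFDist(s2, df1 = df)
  expect_equal(pr$d0, fl$df2, tolerance = 1e-6)
  expect_equal(pr$s02, fl$scale, tolerance = 1e-6)
})

test_that("moderated t reduces to the pooled two-sample t when d0 = 0", {
  cfg <- syntheticConfig(nGenes = 50, onsetFractions = c(0.1, 0, 0), seed = 2)
  sim <- generateStudy(cfg)
  de <- moderatedT(sim$study, "t1", prior = list(d0 = 0, s02 = 1))
  m <- SummarizedExperiment::assay(sim$study, "exprs")
  cd <- SummarizedExperiment::colData(sim$study)
  keep <- cd$timepoint == "t1"
  for (g in sample(rownames(m), 5)) {
    tt <- t.test(m[g, keep & cd$gfp == "pos"], m[g, keep & cd$gfp == "neg"],
                 var.equal = TRUE)
    row <- de[de$gene_id == g, ]
    expect_equal(row$t_mod, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t agrees with the established empirical-Bayes pipeline", {
  cfg <- syntheticConfig(nGenes = 500, onsetFractions = c(0.05, 0, 0),
                         varianceHeterogeneity = 0.5, seed = 14)
  sim <- generateStudy(cfg)
  de <- moderatedT(sim$study, "t1")
  m <- SummarizedExperiment::assay(sim$study, "exprs")
  cd <- SummarizedExperiment::colData(sim$study)
  keep <- cd$timepoint == "t1"
  design <- cbind(1, as.integer(cd$gfp[keep] == "pos"))
  fit <- limma::eBayes(limma::lmFit(m[, keep], design))
  ord <- match(de$gene_id, rownames(m))
  expect_equal(de$log2fc, unname(fit$coefficients[ord, 2]), tolerance = 1e-9)
  expect_gt(cor(de$t_mod, fit$t[ord, 2]), 0.9999)
})

test_that("type I error of the moderated t is calibrated on null genes", {
  cfg <- syntheticConfig(nGenes = 2000, onsetFractions = c(0, 0, 0),
                         noiseSd = 0.5, varianceHeterogeneity = 0.25,
                         seed = 6)
  sim <- generateStudy(cfg)
  de <- moderatedT(sim$study, "t1")
  expect_gt(mean(de$p < 0.05), 0.03)
  expect_lt(mean(de$p < 0.05), 0.07)
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), bruteBH(p))
  }
})

test_that("q-values dominate p-values and respect rank monotonicity", {
  set.seed(5)
  p <- runif(200)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("shrinkage pulls variances toward the prior location", {
  cfg <- syntheticConfig(nGenes = 400, onsetFractions = c(0, 0, 0),
                         varianceHeterogeneity = 0.6, seed = 19)
  sim <- generateStudy(cfg)
  de <- moderatedT(sim$study, "t1")
  pr <- estimatePrior(de$s2, df = 6)
  expect_true(all(abs(de$s2_shrunk - pr$s02) <= abs(de$s2 - pr$s02) + 1e-12))
  expect_true(all(sign(de$t_mod) == sign(de$log2fc) | de$log2fc == 0))
})

test_that("a shared intensity shift leaves fold changes unchanged", {
  cfg <- syntheticConfig(nGenes = 100, onsetFractions = c(0.1, 0, 0), seed = 3)
  sim <- generateStudy(cfg)
  m <- SummarizedExperiment::assay(sim$study, "exprs")
  shifted <- profilingStudy(m + 3,
    as.data.frame(SummarizedExperiment::colData(sim$study)))
  de1 <- moderatedT(sim$study, "t1")
  de2 <- moderatedT(shifted, "t1")
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-12)
})

test_that("enriched calls honor inclusive thresholds and ranking", {
  expect_identical(callEnriched(makeRecords(character(), numeric())),
                   character())
  rec <- makeRecords(c("a", "b", "c", "d"), fc = c(1.5, 3, 3, 1.49),
                     q = c(0.01, 0.001, 0.001, 0.001))
  got <- callEnriched(rec, fcThreshold = 1.5, fdrThreshold = 0.01)
  expect_identical(got, c("b", "c", "a"))  # desc fc, lexicographic ties
  expect_identical(callEnriched(rec, universe = c("b", "d")), "b")
})
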