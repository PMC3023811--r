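test_that("study generation is reproducible and structurally consistent", {
  cfg <- syntheticConfig(nGenes = 300, onsetFractions = c(0.05, 0.03, 0.02),
                         seed = 42)
  a <- generateStudy(cfg)
  b <- generateStudy(cfg)
  expect_identical(SummarizedExperiment::assay(a$study, "exprs"),
                   SummarizedExperiment::assay(b$study, "exprs"))
  expect_identical(deGenes(a$truth), deGenes(b$truth))

  # label consistency: every truth gene exists in the matrix
  expect_true(all(unlist(deGenes(a$truth)) %in% rownames(a$study)))

  # cumulative onset: DE sets nested over time
  dg <- deGenes(a$truth)
  expect_true(all(dg$t1 %in% dg$t2))
  expect_true(all(dg$t2 %in% dg$t3))

  # expected column count: 2 gfp x 3 timepoints x 4 replicates
  expect_equal(ncol(a$study), 24)
})

test_that("transient onset makes per-timepoint DE sets disjoint", {
  cfg <- syntheticConfig(nGenes = 300, onsetFractions = c(0.05, 0.05, 0.05),
                         transientOnset = TRUE, seed = 8)
  dg <- deGenes(generateStudy(cfg)$truth)
  expect_length(intersect(dg$t1, dg$t2), 0)
  expect_length(intersect(dg$t2, dg$t3), 0)
})

test_that("planted genes carry the configured effect; null config carries none", {
  cfg <- syntheticConfig(nGenes = 2000, onsetFractions = c(0.05, 0, 0),
                         effectSize = 2, noiseSd = 0.5,
                         varianceHeterogeneity = 0, seed = 9)
  sim <- generateStudy(cfg)
  m <- SummarizedExperiment::assay(sim$study, "exprs")
  cd <- SummarizedExperiment::colData(sim$study)
  at <- function(tp, gfp) m[, cd$timepoint == tp & cd$gfp == gfp, drop = FALSE]
  diff_t1 <- rowMeans(at("t1", "pos")) - rowMeans(at("t1", "neg"))
  planted <- deGenes(sim$truth)$t1
  # per-gene diff has SE = noiseSd * sqrt(2/4); mean over planted genes
  se <- 0.5 * sqrt(2 / 4) / sqrt(length(planted))
  expect_lt(abs(mean(diff_t1[planted]) - 2), 3 * se)
  nonpl <- setdiff(rownames(m), planted)
  se0 <- 0.5 * sqrt(2 / 4) / sqrt(length(nonpl))
  expect_lt(abs(mean(diff_t1[nonpl])), 3 * se0)

  # zero effect size: labels honored but empirical difference ~ 0
  cfg0 <- syntheticConfig(nGenes = 1000, onsetFractions = c(0.1, 0, 0),
                          effectSize = 0, noiseSd = 0.5,
                          varianceHeterogeneity = 0, seed = 10)
  sim0 <- generateStudy(cfg0)
  m0 <- SummarizedExperiment::assay(sim0$study, "exprs")
  cd0 <- SummarizedExperiment::colData(sim0$study)
  d0 <- rowMeans(m0[, cd0$timepoint == "t1" & cd0$gfp == "pos"]) -
        rowMeans(m0[, cd0$timepoint == "t1" & cd0$gfp == "neg"])
  pl0 <- deGenes(sim0$truth)$t1
  expect_gt(length(pl0), 0)
  expect_lt(abs(mean(d0[pl0])), 3 * 0.5 * sqrt(2 / 4) / sqrt(length(pl0)))
})

test_that("mutant genotype zeroes planted effects for dependent genes only", {
  cfg <- syntheticConfig(nGenes = 800, onsetFractions = c(0.1, 0, 0),
                         effectSize = 2, noiseSd = 0.3,
                         varianceHeterogeneity = 0,
                         mutantDependentFraction = 0.5, seed = 12)
  sim <- generateStudy(cfg, includeMutant = TRUE)
  m <- SummarizedExperiment::assay(sim$study, "exprs")
  cd <- SummarizedExperiment::colData(sim$study)
  dep <- intersect(mutantDependentGenes(sim$truth), deGenes(sim$truth)$t1)
  ind <- setdiff(deGenes(sim$truth)$t1, dep)
  mdiff <- function(geno) {
    keep <- cd$timepoint == "t1" & cd$genotype == geno
    rowMeans(m[, keep & cd$gfp == "pos"]) - rowMeans(m[, keep & cd$gfp == "neg"])
  }
  wt <- mdiff("wildtype"); mut <- mdiff("mutant")
  expect_gt(mean(wt[dep]), 1.5)
  expect_lt(abs(mean(mut[dep])), 0.5)
  expect_gt(mean(mut[ind]), 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(onsetFractions = c(0.6, 0.3, 0.2)), "sum")
  expect_error(syntheticConfig(motifPlantRate = 1.5), "rates")
  expect_error(syntheticConfig(nGenes = 0), "positive")
  expect_error(syntheticConfig(onsetFractions = c(0.1, 0.1)), "per timepoint")
})

test_that("promoter generation plants recoverable motifs and is reproducible", {
  genes <- sprintf("G%05d", 1:60)
  cfg <- syntheticConfig(nGenes = 60, promoterLength = 400,
                         motifPattern = "GCAGSTG", motifPlantRate = 0.8,
                         backgroundMotifRate = 0, seed = 21)
  pr1 <- generatePromoters(cfg, genes, members = list(S = genes[1:50]))
  pr2 <- generatePromoters(cfg, genes, members = list(S = genes[1:50]))
  expect_identical(as.character(pr1$promoters), as.character(pr2$promoters))

  # planted positions excise to concrete expansions of the pattern
  pos <- plantedMotifPositions(pr1$truth)
  win <- as.character(pr1$windows)
  for (g in names(pos)) {
    d <- pos[[g]]
    for (i in seq_len(nrow(d))) {
      frag <- substr(win[[g]], d$offset[i] + 1, d$offset[i] + 7)
      if (d$strand[i] == "-") frag <- bruteRevComp(frag)
      expect_true(nrow(bruteScan(frag, "GCAGSTG", bothStrands = FALSE)) >= 1)
    }
  }

  # hit genes equal planted genes when background rate is zero
  hits <- scanWindows(pr1$windows, "GCAGSTG")
  expect_setequal(hits$gene_id[hits$has_motif], plantedSetMembers(pr1$truth)$S)
})

test_that("promoter saturation and empty-null cases behave as designed", {
  genes <- sprintf("G%05d", 1:10)
  sat <- syntheticConfig(nGenes = 10, promoterLength = 200,
                         motifPlantRate = 1, backgroundMotifRate = 0, seed = 2)
  pr <- generatePromoters(sat, genes, members = list(S = genes))
  hits <- scanWindows(pr$windows, "GCAGSTG")
  expect_true(all(hits$has_motif))

  nul <- syntheticConfig(nGenes = 10, promoterLength = 200,
                         motifPlantRate = 0, backgroundMotifRate = 0, seed = 2)
  pr0 <- generatePromoters(nul, genes, members = list(S = genes))
  hits0 <- scanWindows(pr0$windows, "GCAGSTG")
  expect_true(all(!hits0$has_motif))
  expect_identical(sum(hits0$n_hits), 0L)

  # pattern longer than the window is refused
  bad <- syntheticConfig(nGenes = 10, promoterLength = 5,
                         motifPattern = "GCAGSTG", seed = 1)
  expect_error(generatePromoters(bad, genes), "longer than")
})

test_that("probe alignment fixture encodes its own expected classification", {
  pa <- generateProbeAlignments(nProbesets = 20, oligosPerSet = 14,
                                nPromiscuous = 3, nLowCoverage = 4, seed = 5)
  got <- classifyProbeSets(pa$alignments)
  merged <- merge(got, pa$expected, by = "probeset_id")
  expect_identical(merged$status.x, merged$status.y)
})
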