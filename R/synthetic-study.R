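#' Build a synthetic study configuration
#'
#' Defaults describe a quadruplicate sorted-cell design over three timepoints
#' on a 14,075-gene universe. Onset fractions are cumulative: a gene planted
#' at t1 stays differentially expressed at t2 and t3 (set
#' `transientOnset = TRUE` for onset-only effects).
#'
#' @param nGenes genes in the universe.
#' @param nReplicates replicates per (gfp, timepoint, genotype) condition.
#' @param timepoints ordered timepoint labels.
#' @param onsetFractions fraction of genes newly planted DE at each timepoint.
#' @param effectSize mean log2 fold change (pos minus neg) of planted genes.
#' @param noiseSd per-observation Gaussian SD (log2 scale).
#' @param varianceHeterogeneity SD of the log-normal spread of per-gene SDs.
#' @param transientOnset plant effects only at the onset timepoint.
#' @param mutantDependentFraction fraction of planted genes whose effect is
#'   abolished in the mutant genotype.
#' @param promoterLength promoter window length (bases).
#' @param motifPattern IUPAC consensus planted into member promoters.
#' @param motifPlantRate probability a member promoter carries >= 1 instance.
#' @param backgroundMotifRate per-kb probability of a spurious instance.
#' @param seed integer seed; identical config + seed => identical outputs.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGenes = 14075L, nReplicates = 4L,
                            timepoints = c("t1", "t2", "t3"),
                            onsetFractions = c(0.023, 0.009, 0.008),
                            effectSize = 2, noiseSd = 0.5,
                            varianceHeterogeneity = 0.25,
                            transientOnset = FALSE,
                            mutantDependentFraction = 0.5,
                            promoterLength = 1000L,
                            motifPattern = "GCAGSTG",
                            motifPlantRate = 0.8,
                            backgroundMotifRate = 0.05,
                            seed = 1L) {
  cfg <- methods::new("SyntheticConfig",
    nGenes = as.integer(nGenes), nReplicates = as.integer(nReplicates),
    timepoints = as.character(timepoints),
    onsetFractions = as.numeric(onsetFractions),
    effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
    varianceHeterogeneity = as.numeric(varianceHeterogeneity),
    transientOnset = isTRUE(transientOnset),
    mutantDependentFraction = as.numeric(mutantDependentFraction),
    promoterLength = as.integer(promoterLength),
    motifPattern = toupper(as.character(motifPattern)),
    motifPlantRate = as.numeric(motifPlantRate),
    backgroundMotifRate = as.numeric(backgroundMotifRate),
    seed = as.integer(seed))
  methods::validObject(cfg)
  cfg
}

.geneIds <- function(n) sprintf("G%05d", seq_len(n))

# Per-gene SDs: log-normal spread around noiseSd, mean-corrected so the
# average SD stays at noiseSd as heterogeneity varies.
.geneSds <- function(cfg) {
  if (cfg@varianceHeterogeneity == 0) return(rep(cfg@noiseSd, cfg@nGenes))
  h <- cfg@varianceHeterogeneity
  cfg@noiseSd * exp(stats::rnorm(cfg@nGenes, -h^2 / 2, h))
}

#' Generate a synthetic expression study with known ground truth
#'
#' Simulates log2 intensities for marker-positive ("pos") and marker-negative
#' ("neg") sorted samples at each timepoint, in `nReplicates` per condition.
#' Genes planted DE carry an expected pos-minus-neg log2 difference of
#' `effectSize` from their onset timepoint onward (cumulative model); all
#' other genes have zero expected difference. Noise is additive Gaussian on
#' the log2 scale with per-gene SDs drawn per `varianceHeterogeneity`.
#'
#' With `includeMutant = TRUE` the same design is repeated for a `"mutant"`
#' genotype in which a configured fraction of planted genes have their effect
#' zeroed (these are recorded as `mutantDependentGenes` in the truth object).
#'
#' @param config a [SyntheticConfig-class].
#' @param includeMutant also simulate the mutant genotype.
#' @return A list with elements `study` ([ProfilingStudy-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateStudy(syntheticConfig(nGenes = 200, seed = 7))
#' sim$study
#' @export
generateStudy <- function(config, includeMutant = FALSE) {
  stopifnot(methods::is(config, "SyntheticConfig"))
  methods::validObject(config)
  withr::with_seed(config@seed, .generateStudyImpl(config, includeMutant))
}

.generateStudyImpl <- function(cfg, includeMutant) {
  genes <- .geneIds(cfg@nGenes)
  tps <- cfg@timepoints
  nt <- length(tps)

  # disjoint onset groups
  n_new <- round(cfg@onsetFractions * cfg@nGenes)
  pool <- sample(genes)
  onset <- vector("list", nt)
  taken <- 0L
  for (i in seq_len(nt)) {
    onset[[i]] <- if (n_new[i] > 0) pool[(taken + 1L):(taken + n_new[i])] else character()
    taken <- taken + n_new[i]
  }
  names(onset) <- tps

  de_by_tp <- setNames(vector("list", nt), tps)
  for (i in seq_len(nt)) {
    de_by_tp[[i]] <- if (cfg@transientOnset) onset[[i]] else
      unique(unlist(onset[seq_len(i)], use.names = FALSE))
  }

  planted <- unique(unlist(onset, use.names = FALSE))
  n_dep <- round(cfg@mutantDependentFraction * length(planted))
  mutant_dep <- if (n_dep > 0) sample(planted, n_dep) else character()

  base_mean <- stats::runif(cfg@nGenes, 5, 10)
  sds <- .geneSds(cfg)
  genotypes <- if (includeMutant) c("wildtype", "mutant") else "wildtype"

  cols <- expand.grid(replicate = seq_len(cfg@nReplicates),
                      gfp = c("pos", "neg"), timepoint = tps,
                      genotype = genotypes,
                      stringsAsFactors = FALSE)
  cols$sample_id <- sprintf("%s_%s_%s_r%d",
    ifelse(cols$genotype == "wildtype", "wt", "mut"),
    cols$timepoint, cols$gfp, cols$replicate)

  mat <- matrix(0, cfg@nGenes, nrow(cols),
                dimnames = list(genes, cols$sample_id))
  de_idx <- lapply(de_by_tp, function(g) match(g, genes))
  dep_idx <- match(mutant_dep, genes)

  for (j in seq_len(nrow(cols))) {
    mu <- base_mean
    if (cols$gfp[j] == "pos") {
      idx <- de_idx[[cols$timepoint[j]]]
      if (cols$genotype[j] == "mutant") idx <- setdiff(idx, dep_idx)
      if (length(idx)) mu[idx] <- mu[idx] + cfg@effectSize
    }
    mat[, j] <- mu + stats::rnorm(cfg@nGenes, 0, sds)
  }

  samples <- cols[, c("sample_id", "timepoint", "gfp", "genotype", "replicate")]
  truth <- methods::new("SyntheticTruth",
    deGenes = de_by_tp, setMembers = list(),
    motifPositions = list(),
    mutantDependentGenes = as.character(mutant_dep))
  list(study = profilingStudy(mat, samples), truth = truth)
}

#' Generate synthetic probe-set alignment summaries
#'
#' Emits per-(probe set, gene) oligomer alignment counts with designed clean,
#' promiscuous (two genes each reaching the coverage fraction) and
#' low-coverage (below the fraction) cases, so the trusted-gene classifier can
#' be validated against a known expected classification.
#'
#' @param nProbesets number of clean probe sets (one unique gene each).
#' @param oligosPerSet oligomers per probe set.
#' @param nPromiscuous probe sets whose oligos split evenly across two genes.
#' @param nLowCoverage probe sets with fewer than half their oligos mapped.
#' @param seed integer seed.
#' @return A list with `alignments` (data.frame `probeset_id`, `gene_id`,
#'   `n_oligos_aligned`, `total_oligos`) and `expected` (data.frame
#'   `probeset_id`, `status`, `gene_id` of the designed classification).
#' @export
generateProbeAlignments <- function(nProbesets = 90L, oligosPerSet = 14L,
                                    nPromiscuous = 0L, nLowCoverage = 0L,
                                    seed = 1L) {
  stopifnot(nProbesets >= 0, oligosPerSet >= 2,
            nPromiscuous >= 0, nLowCoverage >= 0)
  withr::with_seed(as.integer(seed), {
    rows <- list(); expected <- list(); g <- 0L
    newGene <- function() { g <<- g + 1L; sprintf("PG%05d", g) }
    ps <- 0L
    newPs <- function() { ps <<- ps + 1L; sprintf("PS%05d", ps) }

    for (i in seq_len(nProbesets)) {
      id <- newPs(); gene <- newGene()
      n_aln <- sample(ceiling(oligosPerSet / 2):oligosPerSet, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        probeset_id = id, gene_id = gene,
        n_oligos_aligned = n_aln, total_oligos = oligosPerSet)
      expected[[length(expected) + 1L]] <- data.frame(
        probeset_id = id, status = "trusted", gene_id = gene)
    }
    for (i in seq_len(nPromiscuous)) {
      id <- newPs(); g1 <- newGene(); g2 <- newGene()
      half <- ceiling(oligosPerSet / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        probeset_id = id, gene_id = c(g1, g2),
        n_oligos_aligned = c(half, half), total_oligos = oligosPerSet)
      expected[[length(expected) + 1L]] <- data.frame(
        probeset_id = id, status = "promiscuous", gene_id = NA_character_)
    }
    for (i in seq_len(nLowCoverage)) {
      id <- newPs(); gene <- newGene()
      n_aln <- sample(seq_len(ceiling(oligosPerSet / 2) - 1L), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        probeset_id = id, gene_id = gene,
        n_oligos_aligned = n_aln, total_oligos = oligosPerSet)
      expected[[length(expected) + 1L]] <- data.frame(
        probeset_id = id, status = "unmapped", gene_id = NA_character_)
    }
    list(alignments = do.call(rbind, rows),
         expected = do.call(rbind, expected))
  })
}
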