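#' @import methods
#' @importFrom stats pnorm pt rnorm runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

#' ProfilingStudy: a log2 expression study with sorted-cell sample metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding a
#' genes x samples matrix of log2 intensities (assay `"exprs"`) together with
#' the sample annotations the pipeline needs: `timepoint` (ordered labels such
#' as t1/t2/t3), `gfp` (`"pos"` for marker-positive sorted cells, `"neg"` for
#' the marker-negative remainder), `genotype` (`"wildtype"` or `"mutant"`) and
#' `replicate`.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("ProfilingStudy", contains = "SummarizedExperiment")

setValidity("ProfilingStudy", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' (log2 intensities) is required")
  need <- c("timepoint", "gfp", "genotype", "replicate")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  else {
    gfp <- SummarizedExperiment::colData(object)$gfp
    if (!all(gfp %in% c("pos", "neg")))
      msg <- c(msg, "gfp must be 'pos' or 'neg'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProfilingStudy
#'
#' @param exprs numeric matrix of log2 intensities, genes as rows (rownames are
#'   gene ids), samples as columns.
#' @param samples data.frame with one row per column of `exprs` and columns
#'   `sample_id`, `timepoint`, `gfp` ("pos"/"neg"), `genotype`, `replicate`.
#' @return A [ProfilingStudy-class] object.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' sm <- data.frame(sample_id = paste0("s", 1:4), timepoint = "t1",
#'   gfp = rep(c("pos", "neg"), each = 2), genotype = "wildtype",
#'   replicate = c(1, 2, 1, 2))
#' profilingStudy(m, sm)
#' @export
profilingStudy <- function(exprs, samples) {
  stopifnot(is.matrix(exprs), ncol(exprs) == nrow(samples))
  if (!is.null(samples$sample_id)) {
    colnames(exprs) <- samples$sample_id
    rownames(samples) <- samples$sample_id
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(samples)
  )
  methods::new("ProfilingStudy", se)
}

#' SyntheticConfig: parameters of the synthetic study generator
#'
#' Defaults emulate a quadruplicate two-channel sorted-cell microarray design
#' over three consecutive timepoints on a 14,075-gene universe, with a
#' cumulative onset model for planted differentially expressed genes.
#'
#' @slot nGenes number of genes in the universe.
#' @slot nReplicates replicates per (gfp, timepoint, genotype) condition.
#' @slot timepoints ordered timepoint labels.
#' @slot onsetFractions fraction of genes planted DE from each timepoint
#'   onward (cumulative onset); must sum to <= 1.
#' @slot effectSize mean log2 fold change (pos minus neg) of planted genes.
#' @slot noiseSd per-observation Gaussian SD on the log2 scale.
#' @slot varianceHeterogeneity SD of the log-normal spread of per-gene SDs
#'   (0 = homoskedastic).
#' @slot transientOnset if TRUE a gene is DE only at its onset timepoint
#'   instead of from onset onward.
#' @slot mutantDependentFraction fraction of planted genes whose effect is
#'   abolished in the mutant genotype.
#' @slot promoterLength promoter window length in bases.
#' @slot motifPattern IUPAC consensus planted in member promoters.
#' @slot motifPlantRate per-gene probability a member promoter carries >= 1
#'   planted instance.
#' @slot backgroundMotifRate per-kb probability that a background promoter
#'   carries a spurious instance.
#' @slot seed integer seed; identical config + seed gives identical output.
#' @export
setClass("SyntheticConfig", representation(
  nGenes = "integer", nReplicates = "integer", timepoints = "character",
  onsetFractions = "numeric", effectSize = "numeric", noiseSd = "numeric",
  varianceHeterogeneity = "numeric", transientOnset = "logical",
  mutantDependentFraction = "numeric", promoterLength = "integer",
  motifPattern = "character", motifPlantRate = "numeric",
  backgroundMotifRate = "numeric", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L || object@nReplicates < 1L || object@promoterLength < 1L)
    msg <- c(msg, "counts must be positive")
  if (length(object@onsetFractions) != length(object@timepoints))
    msg <- c(msg, "one onset fraction per timepoint is required")
  if (any(object@onsetFractions < 0) || sum(object@onsetFractions) > 1)
    msg <- c(msg, "onset fractions must be non-negative and sum to <= 1")
  rates <- c(object@motifPlantRate, object@backgroundMotifRate,
             object@mutantDependentFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (object@noiseSd < 0 || object@varianceHeterogeneity < 0)
    msg <- c(msg, "noiseSd and varianceHeterogeneity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth of a generated study
#'
#' @slot deGenes named list, per timepoint, of planted DE gene ids.
#' @slot setMembers named list of planted gene-set memberships.
#' @slot motifPositions named list, per gene, of data.frames with columns
#'   `offset` (0-based, window-relative, sense strand) and `strand`.
#' @slot mutantDependentGenes gene ids whose DE is abolished in the mutant.
#' @export
setClass("SyntheticTruth", representation(
  deGenes = "list", setMembers = "list", motifPositions = "list",
  mutantDependentGenes = "character"
))

#' EnrichmentResult: a 2x2 over-representation test
#'
#' Overlap of a gene list with a gene set inside a finite universe, with fold
#' enrichment, one-sided upper-tail Fisher exact p and its EASE-corrected
#' variant (overlap decremented by one before taking the tail).
#'
#' @slot k overlap (list AND set).
#' @slot m set size within the universe.
#' @slot n list size.
#' @slot N universe size.
#' @slot fold fold enrichment, (k/m)/(n/N).
#' @slot pFisher one-sided upper-tail hypergeometric p, P(X >= k).
#' @slot pEase Fisher p of the k-1 table (1 when k = 0).
#' @slot significant logical, pFisher < alpha.
#' @slot alpha significance level used for `significant`.
#' @export
setClass("EnrichmentResult", representation(
  k = "integer", m = "integer", n = "integer", N = "integer",
  fold = "numeric", pFisher = "numeric", pEase = "numeric",
  significant = "logical", alpha = "numeric"
))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@k < 0L || object@k > min(object@m, object@n))
    msg <- c(msg, "k must satisfy 0 <= k <= min(m, n)")
  if (object@N < max(object@m, object@n))
    msg <- c(msg, "universe must contain both set and list")
  if (!is.na(object@pEase) && !is.na(object@pFisher) &&
      object@pEase < object@pFisher - 1e-12)
    msg <- c(msg, "pEase must be >= pFisher")
  if (length(msg)) msg else TRUE
})

#' TemporalPartition: Venn regions of three timepoint gene lists
#'
#' @slot regionSets named list over the seven membership labels
#'   `100,010,001,110,101,011,111` (digits mark membership of list 1..3).
#' @slot totals per-timepoint input list sizes.
#' @export
setClass("TemporalPartition", representation(
  regionSets = "list", totals = "integer"
))

setValidity("TemporalPartition", function(object) {
  labs <- c("100", "010", "001", "110", "101", "011", "111")
  if (!identical(sort(names(object@regionSets)), sort(labs)))
    return("regionSets must be named by the 7 membership labels")
  all_genes <- unlist(object@regionSets, use.names = FALSE)
  if (anyDuplicated(all_genes))
    return("regions must be pairwise disjoint")
  TRUE
})

#' ResamplingNull: a resampling null distribution for a list statistic
#'
#' @slot observed score of the real gene list.
#' @slot samples resampled scores (one per iteration).
#' @slot mu null mean (sample mean of `samples`).
#' @slot sigma null SD (n-1 denominator).
#' @slot z (observed - mu) / sigma; NA when degenerate.
#' @slot p one-sided upper-tail normal p; NA when degenerate.
#' @slot pEmpirical rank-based p, (1 + #\{samples >= observed\})/(n_iter + 1).
#' @slot enrichmentFactor observed / mu; NA when mu <= 0.
#' @slot nIter number of resampling iterations.
#' @slot seed integer seed used.
#' @slot degenerate TRUE when sigma is zero (constant statistic).
#' @export
setClass("ResamplingNull", representation(
  observed = "numeric", samples = "numeric", mu = "numeric", sigma = "numeric",
  z = "numeric", p = "numeric", pEmpirical = "numeric",
  enrichmentFactor = "numeric", nIter = "integer", seed = "integer",
  degenerate = "logical"
))

setValidity("ResamplingNull", function(object) {
  msg <- character()
  if (length(object@samples) != object@nIter)
    msg <- c(msg, "length(samples) must equal nIter")
  if (!is.na(object@sigma) && object@sigma < 0)
    msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})
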