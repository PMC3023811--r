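#' Resampling null distribution for a gene-list statistic
#'
#' Scores the observed gene list with a pluggable scorer, then draws
#' `nIter` random gene lists of equal size uniformly without replacement
#' from the universe and scores each, giving a background distribution of
#' the statistic. A normal distribution is fitted to the background (sample
#' mean and SD, n-1 denominator) and the observed score is referred to it
#' by a one-sided upper-tail z-test; the enrichment factor is the observed
#' score over the null mean. A rank-based empirical p is reported alongside
#' as a cross-check on the normal fit.
#'
#' @param list character vector: the observed gene list.
#' @param universe character vector to resample from (must contain at least
#'   `length(list)` genes).
#' @param scorer a `ListScorer` (see [xboxScorer()], [pnsGoScorer()]) or any
#'   function mapping a character vector of gene ids to a non-negative
#'   number, deterministically.
#' @param nIter resampling iterations (>= 100; default 1000).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return A [ResamplingNull-class]. When every resampled score is identical
#'   (sigma = 0) the result is flagged degenerate and z/p are NA.
#' @export
resampleNull <- function(list, universe, scorer, nIter = 1000, seed = 1L) {
  stopifnot(is.function(scorer), nIter >= 100)
  list <- unique(as.character(list))
  universe <- unique(as.character(universe))
  if (length(list) > length(universe))
    stop("list is larger than the universe")
  nIter <- as.integer(nIter)
  seed <- as.integer(seed)
  observed <- as.numeric(scorer(list))
  samples <- withr::with_seed(seed, {
    k <- length(list)
    vapply(seq_len(nIter), function(i)
      as.numeric(scorer(universe[sample.int(length(universe), k)])),
      numeric(1))
  })
  mu <- mean(samples)
  sigma <- stats::sd(samples)
  degenerate <- !is.finite(sigma) || sigma == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sigma
  p <- if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  methods::new("ResamplingNull",
    observed = observed, samples = samples, mu = mu, sigma = sigma,
    z = z, p = p,
    pEmpirical = (1 + sum(samples >= observed)) / (nIter + 1),
    enrichmentFactor = if (mu > 0) observed / mu else NA_real_,
    nIter = nIter, seed = seed, degenerate = degenerate)
}

#' Scorer: number of list genes with a motif
#'
#' Builds a scorer that counts how many genes of a list carry at least one
#' motif hit, from a [scanWindows()] hit table. Genes absent from the table
#' are counted as motif-free.
#'
#' @param hitTable a `MotifHitTable` from [scanWindows()], or any data.frame
#'   with columns `gene_id` and `has_motif`.
#' @return A scoring function (character vector of gene ids -> count).
#' @export
xboxScorer <- function(hitTable) {
  stopifnot(all(c("gene_id", "has_motif") %in% colnames(hitTable)))
  motif_ids <- hitTable$gene_id[as.logical(hitTable$has_motif)]
  function(genes) sum(genes %in% motif_ids)
}

#' Scorer: number of distinct flagged annotation terms hit by a list
#'
#' Builds a scorer that counts the distinct annotation terms flagged as
#' PNS-related that annotate at least one gene of the list.
#'
#' @param annotation data.frame with columns `gene_id`, `term_id`,
#'   `is_pns_related` (0/1).
#' @return A scoring function (character vector of gene ids -> count).
#' @export
pnsGoScorer <- function(annotation) {
  stopifnot(all(c("gene_id", "term_id", "is_pns_related") %in%
                colnames(annotation)))
  flagged <- annotation[annotation$is_pns_related == 1, c("gene_id", "term_id")]
  function(genes) {
    length(unique(flagged$term_id[flagged$gene_id %in% genes]))
  }
}

#' Single-location z-test against a fitted null
#'
#' @param observed observed score.
#' @param mu null mean.
#' @param sigma null SD (> 0).
#' @return list with `z` and the one-sided upper-tail normal `p`.
#' @examples
#' zTest(10, 4, 2)
#' @export
zTest <- function(observed, mu, sigma) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be > 0 (degenerate null)")
  z <- (observed - mu) / sigma
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}
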