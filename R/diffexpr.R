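#' Quantile normalisation of a log2 expression matrix
#'
#' Forces every column onto the same distribution: the across-column mean of
#' order statistics (the quantile step of RMA-style preprocessing). Delegates
#' to [limma::normalizeQuantiles()]. A single-column matrix is returned
#' unchanged.
#'
#' @param x numeric matrix, genes as rows; no missing values.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("missing values are not supported")
  if (ncol(x) <= 1L) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

# Newton inversion of the trigamma function (for prior df estimation).
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Estimate an empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior (degrees of freedom `d0`, location
#' `s02`) to a vector of per-gene sample variances by method of moments on
#' the log scale: under the hierarchical model the log sample variance has
#' mean and variance expressible in digamma/trigamma terms, giving
#' `d0 = 2 * trigammaInverse(var(log s2) - trigamma(df/2))`. When the
#' observed dispersion does not exceed the pure sampling dispersion (or with
#' fewer than 10 genes) the fit degenerates to full pooling: `d0 = Inf`,
#' `s02 = mean(s2)`.
#'
#' @param s2 per-gene sample variances (all > 0 apart from numerical zeros).
#' @param df residual degrees of freedom each variance was estimated with.
#' @return list with `d0` (possibly `Inf`) and `s02`.
#' @export
estimatePrior <- function(s2, df) {
  stopifnot(is.numeric(s2), df >= 1)
  if (all(s2 == 0)) stop("all variances are zero: degenerate input")
  pool <- function() list(d0 = Inf, s02 = mean(s2))
  if (length(s2) < 10L) return(pool())
  z <- log(s2[s2 > 0])
  ex_var <- var(z) - trigamma(df / 2)
  if (!is.finite(ex_var) || ex_var <= 0) return(pool())
  d0 <- 2 * .trigammaInverse(ex_var)
  log_s02 <- mean(z) - digamma(df / 2) + log(df / 2) +
    digamma(d0 / 2) - log(d0 / 2)
  list(d0 = d0, s02 = exp(log_s02))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} min(1, m p_(j) / j)` over
#' the p-values sorted ascending. Wraps [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bhFdr <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Moderated-t differential expression at one timepoint
#'
#' Contrasts marker-positive ("pos") against marker-negative ("neg") samples
#' at one timepoint. Per gene: the log2 fold change is the difference of
#' group means; the pooled sample variance (df = n_pos + n_neg - 2) is
#' shrunk toward the prior, `s2_shrunk = (d0 s02 + df s2) / (d0 + df)`; the
#' moderated t is `log2fc / sqrt(s2_shrunk (1/n_pos + 1/n_neg))` referred to
#' a t distribution on `d0 + df` degrees of freedom (standard normal when
#' `d0 = Inf`). P-values are two-sided; q-values are Benjamini-Hochberg.
#'
#' @param study a [ProfilingStudy-class] (or SummarizedExperiment with the
#'   same colData columns and an `exprs` assay).
#' @param timepoint timepoint label to analyse.
#' @param genotype genotype to analyse (default "wildtype").
#' @param prior optional list with `d0` and `s02`; estimated from the data
#'   with [estimatePrior()] when NULL. `list(d0 = 0)` gives the ordinary
#'   two-sample pooled t.
#' @param fcThreshold linear fold-change threshold for the `enriched` flag.
#' @param fdrThreshold FDR threshold for the `enriched` flag.
#' @return data.frame (one row per gene): `gene_id`, `timepoint`, `log2fc`,
#'   `fc` (= 2^log2fc), `s2`, `s2_shrunk`, `t_mod`, `p`, `q`, `enriched`.
#' @export
moderatedT <- function(study, timepoint, genotype = "wildtype", prior = NULL,
                       fcThreshold = 1.5, fdrThreshold = 0.01) {
  cd <- SummarizedExperiment::colData(study)
  keep <- cd$timepoint == timepoint & cd$genotype == genotype
  if (!any(keep)) stop("no samples at timepoint '", timepoint,
                       "' for genotype '", genotype, "'")
  m <- SummarizedExperiment::assay(study, "exprs")[, keep, drop = FALSE]
  gfp <- cd$gfp[keep]
  n1 <- sum(gfp == "pos"); n2 <- sum(gfp == "neg")
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 replicates per group at ", timepoint)
  pos <- m[, gfp == "pos", drop = FALSE]
  neg <- m[, gfp == "neg", drop = FALSE]
  mean_pos <- rowMeans(pos); mean_neg <- rowMeans(neg)
  log2fc <- mean_pos - mean_neg
  df <- n1 + n2 - 2
  ss <- rowSums((pos - mean_pos)^2) + rowSums((neg - mean_neg)^2)
  s2 <- ss / df
  if (is.null(prior)) prior <- estimatePrior(s2, df)
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s2_shrunk <- rep(prior$s02, length(s2))
    t_mod <- log2fc / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(t_mod))
  } else if (d0 == 0) {
    s2_shrunk <- s2
    t_mod <- log2fc / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_mod), df)
  } else {
    s2_shrunk <- (d0 * prior$s02 + df * s2) / (d0 + df)
    t_mod <- log2fc / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_mod), d0 + df)
  }
  q <- bhFdr(p)
  fc <- 2^log2fc
  data.frame(
    gene_id = rownames(m), timepoint = timepoint,
    log2fc = unname(log2fc), fc = unname(fc), s2 = unname(s2),
    s2_shrunk = unname(s2_shrunk), t_mod = unname(t_mod),
    p = unname(p), q = unname(q),
    enriched = unname(fc >= fcThreshold & q <= fdrThreshold),
    stringsAsFactors = FALSE)
}

#' Genes enriched at a timepoint
#'
#' Genes whose linear fold change and q-value pass the (inclusive)
#' thresholds, optionally restricted to a trusted universe, ordered by
#' descending fold change with ties broken by gene id.
#'
#' @param records output of [moderatedT()] for one timepoint.
#' @param fcThreshold linear fold-change threshold (1.5 or 2 are the usual
#'   choices).
#' @param fdrThreshold FDR threshold (default 0.01).
#' @param universe optional character vector of trusted gene ids.
#' @return Character vector of enriched gene ids, ranked.
#' @export
callEnriched <- function(records, fcThreshold = 1.5, fdrThreshold = 0.01,
                         universe = NULL) {
  if (is.null(records) || nrow(records) == 0) return(character())
  keep <- records$fc >= fcThreshold & records$q <= fdrThreshold
  if (!is.null(universe)) keep <- keep & records$gene_id %in% universe
  hits <- records[keep, c("gene_id", "fc")]
  hits <- hits[order(-hits$fc, hits$gene_id), ]
  hits$gene_id
}
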