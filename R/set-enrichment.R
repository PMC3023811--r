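# Log-space hypergeometric upper tail. Summation over the support in log
# space (logsumexp) keeps extreme tails accurate for universes of ~14,000
# genes, where naive products underflow.
.hyperUpperTail <- function(k, m, n, N) {
  lo <- max(0L, n + m - N)
  hi <- min(m, n)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  x <- k:hi
  lt <- lchoose(m, x) + lchoose(N - m, n - x) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

.newEnrichment <- function(k, m, n, N, alpha) {
  fold <- if (m > 0 && n > 0) (k / m) / (n / N) else NA_real_
  pf <- .hyperUpperTail(k, m, n, N)
  pe <- if (k == 0) 1 else .hyperUpperTail(k - 1L, m, n, N)
  methods::new("EnrichmentResult",
    k = as.integer(k), m = as.integer(m), n = as.integer(n), N = as.integer(N),
    fold = fold, pFisher = pf, pEase = pe,
    significant = is.finite(pf) && pf < alpha, alpha = alpha)
}

#' One-sided Fisher exact over-representation of a gene set in a gene list
#'
#' Tests whether a gene list overlaps a gene set more than expected by
#' chance within a finite universe: `p = P(X >= k)` for X hypergeometric
#' with the set, list and universe sizes as marginals, computed in log
#' space. Fold enrichment is the set's in-list proportion over the
#' genome-wide proportion, `(k/m) / (n/N)`. The EASE-corrected p (the same
#' tail with the overlap decremented by one; 1 when k = 0) is reported
#' alongside.
#'
#' Set and list members outside the universe are dropped before counting.
#'
#' @param list character vector: the gene list (e.g. enriched genes at one
#'   timepoint).
#' @param set character vector: the gene set (e.g. a cilia-database list).
#' @param universe character vector: the trusted-gene universe, or a single
#'   integer N when `list` and `set` are supplied as counts via `k=`.
#' @param alpha significance level for the `significant` flag.
#' @param k,m,n optional explicit counts; when all three are given together
#'   with a scalar integer `universe`, the test is computed from the printed
#'   marginals directly (useful for reproducing published tables).
#' @return An [EnrichmentResult-class].
#' @examples
#' # from printed marginals: 23 of a 28-gene set in a 429-gene list,
#' # universe 14,075
#' fisherEnrichment(universe = 14075, k = 23, m = 28, n = 429)
#' @export
fisherEnrichment <- function(list = NULL, set = NULL, universe, alpha = 0.05,
                             k = NULL, m = NULL, n = NULL) {
  if (!is.null(k)) {
    stopifnot(is.numeric(universe), length(universe) == 1,
              !is.null(m), !is.null(n))
    if (universe < 1) stop("empty universe")
    return(.newEnrichment(k, m, n, universe, alpha))
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  list <- intersect(unique(as.character(list)), universe)
  set <- intersect(unique(as.character(set)), universe)
  .newEnrichment(length(intersect(list, set)), length(set), length(list),
                 length(universe), alpha)
}

#' EASE-corrected Fisher over-representation
#'
#' Identical to [fisherEnrichment()] but the reported headline p-value is
#' the conservative EASE score: the upper-tail Fisher p of the table with
#' the observed overlap decremented by one (p = 1 when the overlap is 0).
#'
#' @inheritParams fisherEnrichment
#' @return An [EnrichmentResult-class] whose `significant` flag is judged on
#'   the EASE p.
#' @export
easeFisher <- function(list = NULL, set = NULL, universe, alpha = 0.05,
                       k = NULL, m = NULL, n = NULL) {
  res <- fisherEnrichment(list, set, universe, alpha, k = k, m = m, n = n)
  methods::initialize(res,
    significant = is.finite(res@pEase) && res@pEase < alpha)
}

# Percent to one decimal, round half up (matches printed table style).
.pct1 <- function(x) floor(x * 10 + 0.5) / 10

#' Table-style over-representation report across timepoints
#'
#' One row per gene set, with per-timepoint overlap counts, percentages of
#' the set (one decimal, half-up) and a significance star when the one-sided
#' Fisher p is below `alpha`; a genome row gives each timepoint's list size
#' and its percentage of the universe. Stars are raw per-row tests (no
#' cross-row multiplicity correction).
#'
#' @param lists named list of character vectors: the enriched gene list per
#'   timepoint.
#' @param collections named list of gene sets (e.g. from [readGmt()]).
#' @param universe trusted-gene universe (character vector).
#' @param alpha significance level for stars.
#' @return data.frame in long form: `set`, `m`, `timepoint`, `n`, `k`,
#'   `percent`, `fold`, `p_fisher`, `p_ease`, `significant`, `cell` (the
#'   formatted "k* (pct%)" string). Sets empty after resolution against the
#'   universe get `testable = FALSE` rows. The genome row appears as set
#'   `"_universe_"`.
#' @export
enrichmentTable <- function(lists, collections, universe, alpha = 0.05) {
  stopifnot(is.list(lists), !is.null(names(lists)),
            is.list(collections), !is.null(names(collections)))
  universe <- unique(as.character(universe))
  rows <- list()
  for (tp in names(lists)) {
    n <- length(intersect(unique(lists[[tp]]), universe))
    rows[[length(rows) + 1L]] <- data.frame(
      set = "_universe_", m = length(universe), timepoint = tp, n = n,
      k = n, percent = .pct1(100 * n / length(universe)), fold = 1,
      p_fisher = NA_real_, p_ease = NA_real_, significant = FALSE,
      testable = TRUE,
      cell = sprintf("%d (%.1f%%)", n, .pct1(100 * n / length(universe))),
      stringsAsFactors = FALSE)
  }
  for (s in names(collections)) {
    set <- intersect(unique(collections[[s]]), universe)
    for (tp in names(lists)) {
      if (length(set) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          set = s, m = 0L, timepoint = tp, n = NA_integer_, k = NA_integer_,
          percent = NA_real_, fold = NA_real_, p_fisher = NA_real_,
          p_ease = NA_real_, significant = FALSE, testable = FALSE,
          cell = "untestable", stringsAsFactors = FALSE)
        next
      }
      res <- fisherEnrichment(lists[[tp]], set, universe, alpha)
      pct <- .pct1(100 * overlapCount(res) / setSize(res))
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, m = setSize(res), timepoint = tp, n = listSize(res),
        k = overlapCount(res), percent = pct, fold = foldEnrichment(res),
        p_fisher = pFisher(res), p_ease = pEase(res),
        significant = isSignificant(res), testable = TRUE,
        cell = sprintf("%d%s (%.1f%%)", overlapCount(res),
                       if (isSignificant(res)) "*" else "", pct),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ranked annotation-term over-representation
#'
#' Tests every annotation term (GO term, protein-domain family, ...) for
#' over-representation in a gene list using the EASE-corrected Fisher p,
#' and returns the most significant terms, ascending by EASE p.
#'
#' @param list character vector: the gene list.
#' @param annotation data.frame with columns `gene_id`, `term_id`,
#'   `term_name` and optionally `is_pns_related` (0/1 flag passed through).
#' @param universe trusted-gene universe.
#' @param top number of terms to return (default 50).
#' @param alpha significance level.
#' @return data.frame: `term_id`, `term_name`, `is_pns_related`, `k`, `m`,
#'   `n`, `fold`, `p_fisher`, `p_ease`, sorted ascending by `p_ease` (ties
#'   by term id), top rows only.
#' @export
termEnrichment <- function(list, annotation, universe, top = 50,
                           alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% colnames(annotation)))
  universe <- unique(as.character(universe))
  list <- intersect(unique(as.character(list)), universe)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  if (!nrow(ann) || !length(intersect(list, ann$gene_id)))
    stop("annotation covers no gene of the list")
  terms <- unique(ann$term_id)
  rows <- lapply(terms, function(tid) {
    sub <- ann[ann$term_id == tid, , drop = FALSE]
    set <- unique(sub$gene_id)
    res <- easeFisher(list, set, universe, alpha)
    data.frame(
      term_id = tid,
      term_name = if ("term_name" %in% colnames(sub)) sub$term_name[1L] else tid,
      is_pns_related = if ("is_pns_related" %in% colnames(sub))
        as.integer(any(sub$is_pns_related == 1)) else NA_integer_,
      k = overlapCount(res), m = setSize(res), n = listSize(res),
      fold = foldEnrichment(res), p_fisher = pFisher(res),
      p_ease = pEase(res), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_ease, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top)
}
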