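#' Classify a probe set by oligomer alignment coverage
#'
#' A probe set mapping to more than one gene (any oligomer aligning to a
#' second gene) is promiscuous and discarded. Otherwise it is trusted for
#' its single gene when at least `minFraction` of its oligomers align to
#' that gene, and unmapped when coverage falls short. The fraction is
#' inclusive at the boundary (>= minFraction).
#'
#' @param perGeneOligoCounts named integer vector: oligomers aligning to each
#'   gene (an oligomer may hit several genes).
#' @param totalOligos total oligomers in the probe set (> 0).
#' @param minFraction coverage fraction required (default 0.5).
#' @return A list with `status` ("trusted", "promiscuous" or "unmapped") and
#'   `gene` (the trusted gene id, or NA).
#' @examples
#' classifyProbeSet(c(geneA = 7), 14)            # trusted: 7/14 >= 0.5
#' classifyProbeSet(c(geneA = 7, geneB = 7), 14) # promiscuous
#' classifyProbeSet(c(geneA = 6), 14)            # unmapped: 6/14 < 0.5
#' @export
classifyProbeSet <- function(perGeneOligoCounts, totalOligos,
                             minFraction = 0.5) {
  if (!is.numeric(totalOligos) || totalOligos <= 0)
    stop("totalOligos must be a positive count")
  stopifnot(is.numeric(perGeneOligoCounts))
  mapped <- perGeneOligoCounts[perGeneOligoCounts > 0]
  if (length(mapped) >= 2L)
    return(list(status = "promiscuous", gene = NA_character_))
  if (length(mapped) == 1L && mapped[[1L]] / totalOligos >= minFraction)
    return(list(status = "trusted", gene = names(mapped)))
  list(status = "unmapped", gene = NA_character_)
}

#' Classify every probe set in an alignment table
#'
#' @param alignments data.frame with columns `probeset_id`, `gene_id`,
#'   `n_oligos_aligned`, `total_oligos` (one row per probeset x gene), as
#'   produced by [generateProbeAlignments()] or read with
#'   [readProbeAlignments()].
#' @param minFraction coverage fraction required (default 0.5).
#' @return data.frame with columns `probeset_id`, `status`, `gene_id`.
#' @export
classifyProbeSets <- function(alignments, minFraction = 0.5) {
  need <- c("probeset_id", "gene_id", "n_oligos_aligned", "total_oligos")
  stopifnot(all(need %in% colnames(alignments)))
  ids <- unique(alignments$probeset_id)
  res <- lapply(ids, function(id) {
    rows <- alignments[alignments$probeset_id == id, ]
    cl <- classifyProbeSet(
      setNames(rows$n_oligos_aligned, rows$gene_id),
      rows$total_oligos[1L], minFraction)
    data.frame(probeset_id = id, status = cl$status,
               gene_id = if (is.na(cl$gene)) NA_character_ else cl$gene,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' The trusted-gene universe
#'
#' Deduplicated union of genes to which at least one probe set is trusted.
#' This set is the universe N for every downstream enrichment test.
#'
#' @param alignments alignment table as for [classifyProbeSets()].
#' @param minFraction coverage fraction required (default 0.5).
#' @return Sorted character vector of trusted gene ids.
#' @export
trustedUniverse <- function(alignments, minFraction = 0.5) {
  if (is.null(alignments) || nrow(alignments) == 0) return(character())
  cl <- classifyProbeSets(alignments, minFraction)
  sort(unique(cl$gene_id[cl$status == "trusted"]))
}

#' Collapse probe-set expression to per-gene expression
#'
#' When several probe sets are trusted to the same gene, the gene's log2
#' intensity is the mean of its probe sets' rows.
#'
#' @param exprs probe-set x sample matrix (rownames are probeset ids).
#' @param classification output of [classifyProbeSets()].
#' @return gene x sample matrix restricted to trusted genes.
#' @export
collapseToGenes <- function(exprs, classification) {
  tr <- classification[classification$status == "trusted" &
                       classification$probeset_id %in% rownames(exprs), ]
  if (!nrow(tr)) return(exprs[0, , drop = FALSE])
  genes <- sort(unique(tr$gene_id))
  out <- matrix(NA_real_, length(genes), ncol(exprs),
                dimnames = list(genes, colnames(exprs)))
  for (g in genes) {
    ps <- tr$probeset_id[tr$gene_id == g]
    out[g, ] <- colMeans(exprs[ps, , drop = FALSE])
  }
  out
}
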