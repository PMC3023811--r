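#' Partition three timepoint gene lists into Venn regions
#'
#' Exact set algebra over the seven non-empty membership regions. Region
#' labels are three digits marking membership of list 1, 2, 3: `100` = genes
#' unique to the first list, `110` = shared by the first two only, `111` =
#' shared by all three, and so on. Genes absent from a list's records are
#' non-members of that list.
#'
#' @param list_t1,list_t2,list_t3 character vectors of gene ids (enriched
#'   gene lists at the three timepoints), drawn from one universe.
#' @param labels timepoint labels for reporting.
#' @return A [TemporalPartition-class].
#' @examples
#' vennPartition(c("a", "b"), c("b", "c"), c("c"))
#' @export
vennPartition <- function(list_t1, list_t2, list_t3,
                          labels = c("t1", "t2", "t3")) {
  l1 <- unique(as.character(list_t1))
  l2 <- unique(as.character(list_t2))
  l3 <- unique(as.character(list_t3))
  all_genes <- unique(c(l1, l2, l3))
  code <- paste0(as.integer(all_genes %in% l1),
                 as.integer(all_genes %in% l2),
                 as.integer(all_genes %in% l3))
  labs <- c("100", "010", "001", "110", "101", "011", "111")
  regions <- setNames(lapply(labs, function(r) sort(all_genes[code == r])),
                      labs)
  part <- methods::new("TemporalPartition",
    regionSets = regions,
    totals = setNames(c(length(l1), length(l2), length(l3)), labels))
  # conservation: per-timepoint total equals the sum of its 4 regions
  counts <- regionCounts(part)
  stopifnot(
    length(l1) == sum(counts[c("100", "110", "101", "111")]),
    length(l2) == sum(counts[c("010", "110", "011", "111")]),
    length(l3) == sum(counts[c("001", "101", "011", "111")]),
    sum(counts) == length(all_genes))
  part
}

#' Fold-change-ranked report for one timepoint
#'
#' The top rows by descending linear fold change, ties broken
#' lexicographically by gene id, with optional set-membership annotation
#' columns (e.g. a cilia-database flag) joined on.
#'
#' @param records [moderatedT()] output for one timepoint (any subset of
#'   rows, e.g. the enriched genes only).
#' @param topN rows to keep (default 100).
#' @param annotations optional named list of gene-id sets; each becomes a
#'   logical membership column.
#' @return data.frame of at most `topN` rows, ranked.
#' @export
rankReport <- function(records, topN = 100, annotations = NULL) {
  if (!is.numeric(topN) || topN <= 0) stop("topN must be positive")
  out <- records[order(-records$fc, records$gene_id), , drop = FALSE]
  out <- head(out, topN)
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    for (nm in names(annotations))
      out[[nm]] <- out$gene_id %in% annotations[[nm]]
  }
  out
}
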