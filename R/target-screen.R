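#' Screen for candidate proneural target genes
#'
#' Contrasts the marker-positive versus marker-negative fold changes of the
#' same genes in wild-type and mutant embryos. A gene passes the primary
#' screen (`passes_s11`) when it is at least `fcThreshold`-fold enriched in
#' wild type (with q <= `fdrThreshold` there) but below `fcThreshold`-fold
#' in the mutant; it passes the stringent screen (`passes_s12`) when
#' additionally the ratio of wild-type to mutant fold changes is at least
#' `ratioThreshold`. Fold changes and the ratio are on the linear scale.
#' Significance in the mutant is not required by default; `strict = TRUE`
#' additionally requires the mutant contrast to be non-significant.
#'
#' Genes present in only one genotype's records are excluded (and reported
#' via a message).
#'
#' @param wt_records,mut_records [moderatedT()] outputs for the same
#'   timepoint in the two genotypes.
#' @param fcThreshold linear fold-change threshold (default 2).
#' @param ratioThreshold wild-type/mutant fold-change ratio threshold
#'   (default 2).
#' @param fdrThreshold FDR required of the wild-type contrast (default 0.01).
#' @param strict also require q > `fdrThreshold` in the mutant.
#' @return data.frame sorted by descending ratio (ties by gene id):
#'   `gene_id`, `fc_wt`, `fc_mut`, `ratio`, `passes_s11`, `passes_s12`.
#' @export
screenTargets <- function(wt_records, mut_records, fcThreshold = 2,
                          ratioThreshold = 2, fdrThreshold = 0.01,
                          strict = FALSE) {
  need <- c("gene_id", "fc", "q")
  stopifnot(all(need %in% colnames(wt_records)),
            all(need %in% colnames(mut_records)))
  common <- intersect(wt_records$gene_id, mut_records$gene_id)
  dropped <- length(setdiff(union(wt_records$gene_id, mut_records$gene_id),
                            common))
  if (dropped > 0)
    message(dropped, " gene(s) present in only one genotype excluded")
  wt <- wt_records[match(common, wt_records$gene_id), ]
  mut <- mut_records[match(common, mut_records$gene_id), ]
  out <- data.frame(
    gene_id = common,
    fc_wt = wt$fc, fc_mut = mut$fc,
    ratio = wt$fc / mut$fc,
    stringsAsFactors = FALSE)
  out$passes_s11 <- out$fc_wt >= fcThreshold & wt$q <= fdrThreshold &
    out$fc_mut < fcThreshold
  if (strict) out$passes_s11 <- out$passes_s11 & mut$q > fdrThreshold
  out$passes_s12 <- out$passes_s11 & out$ratio >= ratioThreshold
  out <- out[order(-out$ratio, out$gene_id), ]
  rownames(out) <- NULL
  out
}
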