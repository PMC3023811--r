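# Readers/writers for the plain-text interchange formats the pipeline uses:
# expression matrix + sample sheet TSV, probe alignment TSV, GMT gene-set
# collections, gene->term annotation TSV, and JSON ground truth.

#' Read an expression study from TSV files
#'
#' @param matrixPath TSV of log2 intensities: genes as rows (first column
#'   gene id), header row of sample ids.
#' @param samplesPath TSV sample sheet with columns `sample_id`, `timepoint`,
#'   `gfp` ("pos"/"neg"), `genotype`, `replicate`.
#' @return A [ProfilingStudy-class].
#' @export
readExpressionStudy <- function(matrixPath, samplesPath) {
  m <- utils::read.delim(matrixPath, row.names = 1, check.names = FALSE)
  samples <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  mat <- as.matrix(m)
  if (!all(samples$sample_id %in% colnames(mat)))
    stop("sample sheet lists samples absent from the matrix")
  profilingStudy(mat[, samples$sample_id, drop = FALSE], samples)
}

#' Write an expression study to TSV files
#'
#' @param study a [ProfilingStudy-class].
#' @param matrixPath,samplesPath output paths (see [readExpressionStudy()]).
#' @return Invisibly, the two paths.
#' @export
writeExpressionStudy <- function(study, matrixPath, samplesPath) {
  m <- SummarizedExperiment::assay(study, "exprs")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(study)),
                     samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, samplesPath))
}

#' Read a probe-set alignment table
#'
#' @param path TSV with columns `probeset_id`, `gene_id`,
#'   `n_oligos_aligned`, `total_oligos` (one row per probeset x gene).
#' @return data.frame suitable for [classifyProbeSets()].
#' @export
readProbeAlignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probeset_id", "gene_id", "n_oligos_aligned", "total_oligos")
  if (!all(need %in% colnames(df)))
    stop("alignment table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set descriptions.
#' @return Invisibly, the path.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`,
#'   `is_pns_related` (0/1).
#' @return data.frame for [termEnrichment()] / [pnsGoScorer()].
#' @export
readAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% colnames(df)))
    stop("annotation table must have gene_id and term_id columns")
  df
}

#' Write synthetic ground truth as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(methods::is(truth, "SyntheticTruth"))
  jsonlite::write_json(list(
    de_genes_by_timepoint = deGenes(truth),
    planted_set_members = plantedSetMembers(truth),
    planted_motif_positions = plantedMotifPositions(truth),
    mutant_dependent_genes = mutantDependentGenes(truth)
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read synthetic ground truth from JSON
#'
#' @param path JSON written by [writeGroundTruth()].
#' @return A [SyntheticTruth-class].
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  toChar <- function(v) if (length(v)) as.character(v) else character()
  pos <- lapply(x$planted_motif_positions, function(d) {
    d <- as.data.frame(d)
    if (!nrow(d)) data.frame(offset = integer(), strand = character(),
                             stringsAsFactors = FALSE)
    else data.frame(offset = as.integer(d$offset),
                    strand = as.character(d$strand),
                    stringsAsFactors = FALSE)
  })
  methods::new("SyntheticTruth",
    deGenes = lapply(x$de_genes_by_timepoint, toChar),
    setMembers = lapply(x$planted_set_members, toChar),
    motifPositions = pos,
    mutantDependentGenes = toChar(x$mutant_dependent_genes))
}

#' Write a differential-expression table
#'
#' Ranked by descending fold change (ties by gene id), the shape of a
#' per-timepoint supplementary table.
#'
#' @param records [moderatedT()] output.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writeDETable <- function(records, path) {
  out <- records[order(-records$fc, records$gene_id),
                 c("gene_id", "fc", "log2fc", "t_mod", "p", "q", "enriched")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
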