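# Synthetic promoter generation: i.i.d. uniform A/C/G/T background scrubbed
# of chance pattern matches, then concrete IUPAC expansions planted at
# non-overlapping offsets (on either strand).

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Vector of random sequences of equal width.
.randomSeqs <- function(count, width) {
  x <- sample(c("A", "C", "G", "T"), count * width, replace = TRUE)
  apply(matrix(x, nrow = width), 2, paste, collapse = "")
}

# Resample any spans matching the pattern (either strand) until the whole
# set is clean.
.scrubSet <- function(seqs, matcher, max_iter = 200L) {
  L <- nchar(matcher$iupac)
  for (it in seq_len(max_iter)) {
    hits <- .scanSet(Biostrings::DNAStringSet(seqs), matcher)
    dirty <- which(vapply(hits, nrow, integer(1)) > 0)
    if (!length(dirty)) return(seqs)
    for (i in dirty) {
      for (off in hits[[i]]$offset)
        substr(seqs[i], off + 1L, off + L) <- .randomBases(L)
    }
  }
  stop("failed to scrub background sequence of pattern matches")
}

# One concrete expansion of an IUPAC consensus.
.sampleInstance <- function(iupac) {
  chars <- .checkIupac(iupac)
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate synthetic promoters with planted motif instances
#'
#' Emits one record per gene: a background sequence of `promoterLength`
#' uniform random bases, scrubbed of chance matches to the configured motif,
#' plus planted concrete expansions of the IUPAC consensus. Members of the
#' supplied gene sets receive a plant with probability `motifPlantRate` (per
#' set); every gene independently receives a spurious background instance
#' with per-kb probability `backgroundMotifRate`. Instances are planted at
#' uniformly chosen non-overlapping offsets, on a random strand; minus-strand
#' plants appear reverse complemented in the emitted sequence.
#'
#' Each emitted FASTA record is the `promoterLength`-base promoter followed
#' by the single TSS base, so the TSS annotation stays within the contig.
#' Roughly half the genes are emitted in minus-strand orientation (the
#' stored contig is the reverse complement of the promoter) to exercise
#' strand handling; [extractWindows()] over the emitted sequences and TSS
#' returns the sense-strand promoter windows exactly.
#'
#' @param config a [SyntheticConfig-class] (uses `promoterLength`,
#'   `motifPattern`, `motifPlantRate`, `backgroundMotifRate`, `seed`).
#' @param genes character vector of gene ids (the promoter universe).
#' @param members named list of gene sets (subsets of `genes`) whose member
#'   promoters are candidates for motif planting.
#' @return A list with `promoters` (DNAStringSet, one contig per gene),
#'   `tss` (GRanges, one single-base TSS record per gene, with `name`),
#'   `windows` (DNAStringSet of the sense-strand promoter windows as
#'   generated) and `truth` ([SyntheticTruth-class] with `motifPositions`
#'   per gene and `plantedSetMembers` recording which members actually
#'   received a set plant).
#' @export
generatePromoters <- function(config, genes, members = list()) {
  stopifnot(methods::is(config, "SyntheticConfig"), is.character(genes))
  methods::validObject(config)
  if (nchar(config@motifPattern) > config@promoterLength)
    stop("motif pattern is longer than the promoter window")
  if (length(members) && !all(unlist(members) %in% genes))
    stop("gene-set members must be drawn from `genes`")
  withr::with_seed(config@seed, .generatePromotersImpl(config, genes, members))
}

.generatePromotersImpl <- function(cfg, genes, members) {
  w <- cfg@promoterLength
  matcher <- compilePattern(cfg@motifPattern, bothStrands = TRUE)
  L <- nchar(cfg@motifPattern)

  windows <- setNames(.scrubSet(.randomSeqs(length(genes), w), matcher),
                      genes)

  positions <- setNames(vector("list", length(genes)), genes)
  empty_pos <- data.frame(offset = integer(), strand = character(),
                          stringsAsFactors = FALSE)
  for (g in genes) positions[[g]] <- empty_pos

  plant <- function(g) {
    existing <- positions[[g]]$offset
    ok <- setdiff(0:(w - L), unlist(lapply(existing, function(o)
      (o - L + 1L):(o + L - 1L))))
    if (!length(ok)) return(FALSE)
    off <- ok[sample.int(length(ok), 1L)]
    str <- sample(c("+", "-"), 1L)
    inst <- .sampleInstance(cfg@motifPattern)
    emit <- if (str == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
      else inst
    s <- windows[[g]]
    substr(s, off + 1L, off + L) <- emit
    windows[[g]] <<- s
    positions[[g]] <<- rbind(positions[[g]],
      data.frame(offset = off, strand = str, stringsAsFactors = FALSE))
    TRUE
  }

  # spurious background instances
  p_bg <- cfg@backgroundMotifRate * w / 1000
  for (g in genes) if (stats::runif(1) < p_bg) plant(g)

  # planted set instances
  planted_members <- setNames(vector("list", length(members)), names(members))
  for (s in names(members)) {
    got <- character()
    for (g in members[[s]]) {
      if (stats::runif(1) < cfg@motifPlantRate && plant(g)) got <- c(got, g)
    }
    planted_members[[s]] <- got
  }

  # assemble contigs: half plus, half minus orientation
  strands <- sample(c("+", "-"), length(genes), replace = TRUE)
  tssbases <- sample(c("A", "C", "G", "T"), length(genes), replace = TRUE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unlist(windows))))
  contigs <- ifelse(strands == "+",
                    paste0(unlist(windows), tssbases),
                    paste0(tssbases, rc))
  tss0 <- ifelse(strands == "+", w, 0L)  # 0-based TSS coordinate
  proms <- Biostrings::DNAStringSet(setNames(contigs, genes))
  tss <- GenomicRanges::GRanges(
    seqnames = genes,
    ranges = IRanges::IRanges(start = tss0 + 1L, width = 1L),
    strand = strands, name = genes, score = 0L)

  truth <- methods::new("SyntheticTruth",
    deGenes = list(), setMembers = planted_members,
    motifPositions = positions, mutantDependentGenes = character())
  list(promoters = proms, tss = tss,
       windows = Biostrings::DNAStringSet(windows), truth = truth)
}
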