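IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.checkIupac <- function(iupac) {
  chars <- strsplit(toupper(iupac), "")[[1]]
  if (length(chars) == 0)
    stop("empty motif pattern")
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  chars
}

.revCompIupac <- function(iupac) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
}

#' Compile an IUPAC consensus into a motif matcher
#'
#' @param iupac consensus string over the 15-letter IUPAC DNA alphabet
#'   (e.g. `"CANNTG"` for the E box, `"GCAGSTG"` for the Scute site).
#' @param name optional motif name carried through to reports.
#' @param bothStrands scan both strands (default). A pattern that equals its
#'   own reverse complement at the IUPAC level (such as `CANNTG`) is scanned
#'   on the plus strand only, so each genomic site is counted once.
#' @return An object of class `MotifMatcher` with the pattern, its reverse
#'   complement, and the strand policy.
#' @examples
#' compilePattern("GCAGSTG", name = "sc_site")
#' @export
compilePattern <- function(iupac, name = iupac, bothStrands = TRUE) {
  .checkIupac(iupac)
  iupac <- toupper(iupac)
  rc <- .revCompIupac(iupac)
  structure(list(name = name, iupac = iupac, rc = rc,
                 bothStrands = isTRUE(bothStrands),
                 palindromic = identical(iupac, rc)),
            class = "MotifMatcher")
}

#' @export
print.MotifMatcher <- function(x, ...) {
  cat(sprintf("MotifMatcher '%s': %s (rev comp %s), %s\n", x$name, x$iupac,
      x$rc, if (!x$bothStrands) "plus strand only"
            else if (x$palindromic) "both strands (palindromic, counted once)"
            else "both strands"))
  invisible(x)
}

# All match start positions (0-based) of one pattern string across a
# DNAStringSet, as a list parallel to the set. Windows shorter than the
# pattern cannot match.
.vscanOffsets <- function(subjects, pat) {
  offs <- vector("list", length(subjects))
  long <- Biostrings::width(subjects) >= nchar(pat)
  if (any(long)) {
    mi <- Biostrings::vmatchPattern(pat, subjects[long], fixed = FALSE)
    si <- Biostrings::startIndex(mi)
    offs[long] <- lapply(si, function(s) if (is.null(s)) integer() else s - 1L)
  }
  offs[!long] <- list(integer())
  offs
}

# Per-sequence (offset, strand) hit tables for a compiled matcher.
.scanSet <- function(subjects, matcher) {
  plus <- .vscanOffsets(subjects, matcher$iupac)
  minus <- if (matcher$bothStrands && !matcher$palindromic)
    .vscanOffsets(subjects, matcher$rc) else rep(list(integer()),
                                                 length(subjects))
  Map(function(p, m) data.frame(
    offset = c(p, m),
    strand = rep(c("+", "-"), c(length(p), length(m))),
    stringsAsFactors = FALSE), plus, minus)
}

# Single-sequence convenience used by the synthetic generator.
.scanOne <- function(text, matcher) {
  .scanSet(Biostrings::DNAStringSet(text), matcher)[[1L]]
}

#' Scan promoter windows for a motif
#'
#' Counts all (possibly overlapping) matches of an IUPAC consensus in each
#' window, on both strands unless the matcher says otherwise.
#'
#' @param windows a named [Biostrings::DNAStringSet] (names are gene ids) or
#'   a named character vector of sequences, each read 5'->3' on the gene's
#'   sense strand toward the TSS.
#' @param pattern a `MotifMatcher` from [compilePattern()], or an IUPAC string.
#' @return A `MotifHitTable`: data.frame with columns `gene_id`, `n_hits`,
#'   `has_motif`, carrying the per-site detail as `attr(, "sites")`
#'   (data.frame `gene_id`, `offset`, `strand`; offsets 0-based,
#'   window-relative, sense strand).
#' @examples
#' hits <- scanWindows(c(gA = "TTGCAGCTGTT", gB = "AAAAAAA"), "GCAGSTG")
#' hits
#' motifSites(hits)
#' @export
scanWindows <- function(windows, pattern) {
  if (is.character(pattern)) pattern <- compilePattern(pattern)
  stopifnot(inherits(pattern, "MotifMatcher"))
  if (!methods::is(windows, "DNAStringSet")) {
    stopifnot(is.character(windows))
    windows <- Biostrings::DNAStringSet(windows)
  }
  stopifnot(!is.null(names(windows)))
  per_gene <- setNames(.scanSet(windows, pattern), names(windows))
  n_hits <- vapply(per_gene, nrow, integer(1))
  parts <- Filter(Negate(is.null), Map(function(g, d)
    if (nrow(d)) cbind(gene_id = g, d, stringsAsFactors = FALSE) else NULL,
    names(per_gene), per_gene))
  sites <- if (length(parts)) do.call(rbind, parts) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  out <- data.frame(gene_id = names(windows), n_hits = unname(n_hits),
                    has_motif = unname(n_hits) >= 1L,
                    stringsAsFactors = FALSE)
  attr(out, "sites") <- sites
  attr(out, "motif") <- pattern$name
  class(out) <- c("MotifHitTable", class(out))
  out
}

#' Per-site detail of a motif scan
#'
#' @param hits a `MotifHitTable` from [scanWindows()].
#' @return data.frame with columns `gene_id`, `offset`, `strand`.
#' @export
motifSites <- function(hits) {
  stopifnot(inherits(hits, "MotifHitTable"))
  attr(hits, "sites")
}

#' Extract upstream promoter windows from sequences and TSS annotation
#'
#' For plus-strand genes the window is the `windowBp` bases immediately
#' upstream of (and excluding) the TSS base; for minus-strand genes the
#' `windowBp` bases immediately downstream, reverse complemented. All
#' coordinates are 0-based half-open internally; windows are clipped at
#' contig ends. The returned sequences read 5'->3' on the gene's sense
#' strand toward the TSS.
#'
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param tss path to a BED6 file (0-based half-open, strand in column 6) or
#'   a [GenomicRanges::GRanges] with a `name` column; each record marks the
#'   single TSS base of one gene.
#' @param windowBp window length in bases (1000 and 2000 are the usual
#'   choices).
#' @return A named [Biostrings::DNAStringSet] of windows, one per BED record,
#'   named by the record's `name`.
#' @export
extractWindows <- function(fasta, tss, windowBp = 1000L) {
  stopifnot(windowBp >= 1)
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- if (methods::is(tss, "GRanges")) tss else rtracklayer::import(tss)
  if (is.null(gr$name)) gr$name <- as.character(seq_along(gr))
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    contig <- as.character(GenomicRanges::seqnames(gr)[i])
    if (!contig %in% names(seqs))
      stop("TSS record '", gr$name[i], "' references missing contig '",
           contig, "'")
    s <- seqs[[contig]]
    len <- length(s)
    t0 <- GenomicRanges::start(gr)[i] - 1L  # 0-based TSS coordinate
    str <- as.character(GenomicRanges::strand(gr)[i])
    if (str == "-") {
      from <- t0 + 1L
      to <- min(len - 1L, t0 + windowBp)
      win <- if (from > to) Biostrings::DNAString("") else
        Biostrings::reverseComplement(Biostrings::subseq(s, from + 1L, to + 1L))
    } else {
      from <- max(0L, t0 - windowBp)
      to <- t0 - 1L
      win <- if (from > to) Biostrings::DNAString("") else
        Biostrings::subseq(s, from + 1L, to + 1L)
    }
    out[[i]] <- win
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- gr$name
  res
}

#' Rewrite E boxes for mutagenesis constructs
#'
#' Every plus-strand occurrence of the E box `CANNTG` is rewritten to
#' `AANNTT` (first base C->A, last base G->T, middle bases preserved),
#' scanning left to right. After a rewrite, scanning resumes at the base
#' following the start of the rewritten match, so occurrences created by a
#' rewrite are themselves rewritten; the result contains no plus-strand
#' `CANNTG` match.
#'
#' @param sequence a DNA string (character scalar).
#' @return The mutagenised sequence (same length).
#' @examples
#' mutateEbox("CAGGTG")   # "AAGGTT"
#' @export
mutateEbox <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  i <- 1L
  while (i <= n - 5L) {
    if (chars[i] == "C" && chars[i + 1L] == "A" &&
        chars[i + 4L] == "T" && chars[i + 5L] == "G") {
      chars[i] <- "A"
      chars[i + 5L] <- "T"
    }
    i <- i + 1L
  }
  paste(chars, collapse = "")
}
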