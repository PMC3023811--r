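# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain choose() sums, double loops, and character
# comparisons.

# Hypergeometric upper tail by direct enumeration over the support.
bruteHyperTail <- function(k, m, n, N) {
  lo <- max(0, n + m - N)
  hi <- min(m, n)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  x <- k:hi
  sum(choose(m, x) * choose(N - m, n - x)) / choose(N, n)
}

# Benjamini-Hochberg step-up by brute-force double loop:
# q_i = min over all j with p_j >= p_i of min(1, m * p_j / rank(p_j)).
bruteBH <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) cand <- min(cand, min(1, m * p[j] / r[j]))
    }
    q[i] <- cand
  }
  q
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

bruteRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Sliding-window IUPAC match, both strands, same site-counting convention as
# the package (palindromic IUPAC pattern counted on plus strand only).
bruteScan <- function(text, iupac, bothStrands = TRUE) {
  tc <- strsplit(toupper(text), "")[[1]]
  matchAt <- function(pat) {
    pc <- strsplit(pat, "")[[1]]
    L <- length(pc); n <- length(tc)
    if (n < L) return(integer())
    ok <- rep(TRUE, n - L + 1)
    for (j in seq_len(L))
      ok <- ok & tc[j:(n - L + j)] %in% IUPAC_SETS[[pc[j]]]
    which(ok) - 1L
  }
  rc <- bruteRevComp(toupper(iupac))
  plus <- matchAt(toupper(iupac))
  minus <- if (bothStrands && !identical(rc, toupper(iupac))) matchAt(rc)
           else integer()
  data.frame(offset = c(plus, minus),
             strand = rep(c("+", "-"), c(length(plus), length(minus))),
             stringsAsFactors = FALSE)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal DE-record table for ranking / screening tests.
makeRecords <- function(gene_id, fc, q = rep(0.001, length(fc)),
                        timepoint = "t1") {
  n <- length(gene_id)
  data.frame(gene_id = as.character(gene_id),
             timepoint = rep(timepoint, n),
             log2fc = log2(fc), fc = fc, s2 = rep(0.1, n),
             s2_shrunk = rep(0.1, n), t_mod = rep(1, n), p = q, q = q,
             enriched = rep(TRUE, n), stringsAsFactors = FALSE)
}
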