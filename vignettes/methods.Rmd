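---
title: "Methods: temporal profiling of sensory precursor lineages"
author: "tempro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal profiling of sensory precursor lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempro)
```

# The analysis problem

Proneural bHLH transcription factors such as *atonal* commit ectodermal
cells to sensory-organ-precursor fate, but are expressed only transiently;
the differentiation program they set in motion — notably ciliogenesis of the
chordotonal neuron's sensory dendrite — unfolds over the following hours
through intermediate regulators such as RFX (acting on X-box motifs) and
lineage-specific factors. `tempro` implements the computational side of a
study design that probes this cascade: marker-positive (GFP-sorted)
precursor cells versus the marker-negative remainder, profiled at three
consecutive timepoints in quadruplicate, in wild-type and proneural-mutant
genotypes, followed by gene-set, promoter-motif and target-screen analyses.

The package operates downstream of array preprocessing: its input is a
genes × samples matrix of log2 intensities (a quantile-normalisation step
is provided via `quantileNormalize()`; background correction and
probe-level summarisation are out of scope).

# Trusted genes

Probe sets are mapped to genes by oligomer alignment counts. A probe set
mapping to more than one gene (any oligomer hitting a second gene) is
*promiscuous* and discarded; a single-gene probe set is *trusted* when at
least 50% of its oligomers align (inclusive at exactly 0.5), otherwise
*unmapped*. The union of trusted genes is the analysis universe for every
enrichment test. Where several probe sets are trusted to the same gene,
their rows are collapsed by the per-gene mean log2 intensity
(`collapseToGenes()`); the combiner is not dictated by the filtering rule,
and the mean is the least-informative symmetric choice on the log scale.
Under these definitions, raising the coverage fraction can only shrink the
trusted set — a useful sanity invariant that would not hold if promiscuity
itself were judged against the coverage fraction.

# Differential expression

For each timepoint (and genotype), per-gene log2 fold change is the
difference of group means between sorted-positive and sorted-negative
samples. Per-gene sample variances $s^2_g$ (pooled within groups,
$d = n_+ + n_- - 2$ residual df) are shrunk toward an empirical-Bayes prior,

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},\qquad
t_g = \frac{\widehat{\mathrm{lfc}}_g}{\sqrt{\tilde s^2_g (1/n_+ + 1/n_-)}},$$

with $t_g$ referred to a t distribution on $d_0 + d$ df. The prior
$(d_0, s_0^2)$ is a scaled inverse-chi-square fitted by method of moments on
the log scale: under the hierarchical model,
$\operatorname{Var}(\log s^2_g) = \psi'(d/2) + \psi'(d_0/2)$, so
$d_0 = 2\,\psi'^{-1}\!\big(\operatorname{Var}(\log s^2) - \psi'(d/2)\big)$
(trigamma inversion by Newton iteration), and $s_0^2$ follows from the mean
of $\log s^2$ via digamma terms. When the observed dispersion does not
exceed pure sampling dispersion — including the degenerate all-equal case —
the fit falls back to full pooling ($d_0 = \infty$, $s_0^2$ = mean
variance, normal reference distribution). Fewer than 10 genes also pool.
The estimator cannot resolve $d_0$ below the trigamma branch it inverts on,
but parameter recovery is accurate in the regime that matters (the test
suite recovers $d_0 = 4$ from $10^4$ genes within [2.5, 6]).

P-values are two-sided; "enriched" is then one-directional by gating on the
linear fold change $2^{\mathrm{lfc}} \ge$ threshold (1.5 or 2), with
Benjamini–Hochberg q-values at a 1% FDR. Both thresholds are inclusive.
Ranked reports order by descending fold change with lexicographic gene-id
tie-breaks, so output is deterministic.

# Temporal set analysis

Per-timepoint enriched gene lists are partitioned by exact set algebra into
the seven Venn regions (`vennPartition()`); the partition asserts its own
conservation invariants (disjoint regions, per-timepoint totals) on every
run. Lists, not matrices, are the unit: a gene absent from one timepoint's
records is simply a non-member of that list.

# Over-representation statistics

`fisherEnrichment()` computes the one-sided upper-tail Fisher exact
(hypergeometric) p, summed in log space (logsumexp over `lchoose` terms) so
that tails of order $10^{-30}$ at a universe of ~14,000 genes remain
accurate. Fold enrichment is $(k/m)/(n/N)$. The EASE-corrected p
(`easeFisher()`) is the same tail with the observed overlap decremented by
one — conservative by construction ($p_{\mathrm{EASE}} \ge
p_{\mathrm{Fisher}}$, equality of $p_{\mathrm{EASE}}(k)$ with
$p_{\mathrm{Fisher}}(k-1)$ is asserted property-style in the tests).
One-sided tests are the default because the scientific question is
over-representation only; a table cell is starred at raw $p < 0.05$ with no
cross-row multiplicity correction, matching the reporting convention of the
summary-table style it reproduces. Percentages are formatted to one decimal
with half-up rounding. Gene-set members that do not resolve against the
universe are dropped before the set size $m$ is counted, because the table
percentages use set totals as denominators. Annotation-term reports
(`termEnrichment()`) rank ascending by EASE p and return the top 50 terms
by default; protein-domain families are handled as just another gene-set
collection, with no separate code path. GO-graph propagation is out of
scope; annotations are taken as given.

# Motif scanning

Patterns are IUPAC consensus strings (E box `CANNTG`, Scute site `GCAGSTG`,
and user-supplied X-box / ato-specific E-box consensi — the latter two are
deliberately not hard-coded, since their sequence definitions belong to
their source databases and should be supplied by the analyst). Scanning
(`scanWindows()`, built on Biostrings) reports every match offset
(0-based, window-relative, 5'→3' on the gene's sense strand) on both
strands; a pattern that equals its own reverse complement at the IUPAC
level (e.g. `CANNTG`) is scanned on the plus strand only so each genomic
site is counted exactly once. Promoter windows (`extractWindows()`) are the
`windowBp` bases upstream of the TSS — BED6 input, 0-based half-open,
strand-aware, clipped at contig edges, reverse complemented for minus-strand
genes. 1 kb and 2 kb are the intended window sizes.

`mutateEbox()` reproduces a site-directed mutagenesis design: every
plus-strand `CANNTG` is rewritten to `AANNTT` scanning left to right, with
scanning resuming at the base after each rewritten match's start. That
cursor rule matters: a rewrite can create a new E box overlapping the old
one (e.g. `CACATGTG` → `AACATTTG`, which contains `CATTTG`), and the chosen
rule provably leaves no plus-strand E box in the output (a rewrite
introduces only A and T at the changed positions, which can never complete
a match starting before the cursor).

# Resampling nulls

List-level enrichment questions ("do these genes carry X boxes more often
than chance?", "do they hit more PNS-related annotation terms?") are
answered by a generic resampling engine: draw `nIter` random gene lists of
the same size uniformly without replacement from the universe, score each
with a pluggable statistic, fit a normal distribution (sample mean/SD,
n−1), and refer the observed score to it with a one-sided upper-tail
z-test; the enrichment factor is observed/null-mean. The observed list is
not excluded from the resampling pool — random lists "of equal size" are
taken literally. A rank-based empirical p is reported alongside as a check
on the normal fit, and a constant statistic is flagged degenerate rather
than producing infinite z. `nIter` defaults to 1000.

Because the scores are small discrete counts, the normal-fit z-test is
slightly anti-conservative near its design point: at a background motif
fraction of 0.05 and list size 50 (null mean 2.5), its true size at nominal
5% is about 0.065 rather than 0.050 — a property of fitting a continuous
distribution to a skewed count, not of the implementation. The calibration
test therefore estimates the rejection rate over several thousand replicate
draws so that Monte Carlo error does not dominate the comparison.

# Target screen

Candidate proneural targets are genes ≥2-fold enriched (at 1% FDR) in the
wild-type contrast but <2-fold in the mutant contrast; the stringent tier
additionally requires the wild-type/mutant fold-change ratio to be ≥2.
"<2-fold in the mutant" is interpreted as a fold-change magnitude
condition — mutant significance is neither required nor forbidden — because
that is what the selection wording says; a `strict` flag additionally
requires mutant non-significance for analysts who prefer it. Ratios are
computed on linear fold changes. Genes quantified in only one genotype are
excluded and counted.

# The synthetic-data generator

Every statistical claim in the test suite is made against data with known
ground truth from `generateStudy()` / `generatePromoters()` /
`generateProbeAlignments()`.

**What it emulates.** A 14,075-gene universe; two sorted fractions at three
timepoints in quadruplicate (optionally × two genotypes); additive Gaussian
noise on the log2 scale (the natural scale for RMA-style intensities);
genes planted differentially expressed from an onset timepoint onward
(cumulative, matching a developmental cascade; a transient mode exists
because real temporal lists contain both shared and unique genes); per-gene
SDs spread log-normally around the noise SD; a mutant genotype identical
except that a configured fraction of planted genes lose their effect
(modelling failed specification of the sorted cells); promoters of i.i.d.
uniform bases carrying planted concrete expansions of an IUPAC consensus at
non-overlapping offsets on either strand.

**Defaults.** Effect size 2 (log2; a 4-fold change, typical of the strong
top-ranked genes such designs highlight), noise SD 0.5, variance
heterogeneity 0.25 (mild gene-to-gene spread), onset fractions
(0.023, 0.009, 0.008) so that the three lists have the few-hundred-gene
scale of the motivating design at the full universe size, motif plant rate
0.8, background motif rate 0.05/kb, mutant-dependent fraction 0.5. All
rates and sizes are configurable; identical config + seed gives
byte-identical output.

**What it does not emulate.** Probe-level intensities, background
correction, batch or sort-run effects, correlated replicates (independence
between sorted fractions from the same run is assumed, as nothing in the
design specifies otherwise), promoter base composition (background is
uniform; composition bias is out of scope), and overlapping or clustered
motif sites. Passing benchmarks on these data therefore validate the
statistical machinery — recovery of planted effects, calibration of null
distributions, exactness of set arithmetic — not robustness to array
artefacts.

**A scrubbing subtlety.** Uniform random sequence contains short consensus
matches by chance (an E box every ~130 bp per strand), which would make
"zero planted motifs" unrealisable. The generator therefore resamples any
spans of the background matching the configured pattern (on either strand)
before planting, so that the emitted hit set equals the planted truth
exactly when the background rate is zero. Background "spurious" instances
are then re-introduced at the configured per-kb rate, as deliberate plants
recorded in the ground truth. Emitted FASTA records are the promoter plus
the single TSS base (so the TSS annotation stays within its contig), with
about half the genes emitted in minus-strand orientation to exercise strand
handling end to end.

# Benchmark problem sizes

The shipped tests and the acceptance script use: 2,000-gene universes for
DE recovery and target screens (40–120 planted genes, 4v4 replicates);
the full 14,075-gene universe for one default-scale pipeline run;
exhaustive enumeration of all contingency tables up to a universe of 60
for the Fisher oracle; 10^3–10^4 random cases for the BH, EASE and
motif-scan oracles; and thousands of (universe, list) replicates at
`nIter = 1000` for z-test calibration, for the discreteness reason above.
These sizes were chosen so every planted signal is comfortably detectable
by the method under test while each suite stays quick to run.

# Known limitations

* The prior estimator is a log-scale method of moments; it matches the
  established empirical-Bayes implementation on well-behaved data but does
  not implement robustified or trended variants.
* Printed-table reproduction computes from whatever counts are supplied;
  where a source's own text and table disagree on a marginal count, the
  package does not arbitrate.
* The normal-fit z-test inherits the discreteness caveat above; for very
  small expected counts the reported empirical p is the safer quantity.
* IUPAC scanning is exact-match consensus only — no PWM scoring, no
  cross-species conservation filtering (conserved-motif gene lists are
  consumed as precomputed gene sets).
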