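# tempro

Temporal expression profiling of sensory precursor lineages — an R
(Bioconductor-style) package for the analysis pipeline downstream of a
sorted-cell developmental time-course microarray study.

## The problem

A proneural transcription factor (such as *Drosophila* *atonal*) is
expressed only transiently when a sense-organ precursor is specified, yet
it sets in motion hours of downstream differentiation — most prominently
ciliogenesis of the chordotonal neuron's sensory dendrite, mediated by
intermediate regulators such as RFX acting through X-box promoter motifs.
The study design this package serves contrasts marker-positive (GFP-sorted)
precursor cells against the marker-negative remainder at three consecutive
timepoints (quadruplicate arrays), in wild-type and proneural-mutant
embryos, and asks:

* which genes are enriched in the precursor lineage at each timepoint
  (moderated t, fold-change ≥ 1.5 or 2, BH-FDR ≤ 1%), restricted to a
  *trusted-gene* universe (probe sets mapping uniquely to one gene with
  ≥ 50% of their oligomers);
* how the per-timepoint lists partition over time (Venn regions, ranked
  fold-change reports);
* whether curated gene sets (cilia/basal-body databases, conserved X-box
  target lists, GO terms, protein-domain families) are over-represented —
  one-sided Fisher exact test with fold enrichment $(k/m)/(n/N)$ and the
  conservative EASE variant (overlap decremented by one);
* whether promoter windows (1–2 kb upstream of the TSS) carry IUPAC
  consensus motifs (X boxes, E boxes `CANNTG`, Scute sites `GCAGSTG`) more
  often than random gene lists of equal size — a resampling null with a
  one-sided z-test and enrichment factor against the null mean;
* which genes are candidate direct proneural targets: ≥ 2-fold enriched in
  wild type (1% FDR) but < 2-fold in the mutant, with a stringent tier
  requiring a ≥ 2-fold wild-type/mutant fold-change ratio.

A synthetic-data module (`syntheticConfig()`, `generateStudy()`,
`generatePromoters()`, `generateProbeAlignments()`) generates complete
studies with planted ground truth — DE genes with early/mid/late onset,
mutant-dependent effects, gene-set memberships and promoter motif
instances — so every stage is benchmarked against a recoverable signal.

## Worked example

```r
library(tempro)

# a synthetic study with planted truth: 2,000 genes, 4v4 replicates,
# 2% of genes newly DE at each timepoint (log2 effect 2, noise SD 0.5)
cfg <- syntheticConfig(nGenes = 2000, onsetFractions = c(0.02, 0.02, 0.02),
                       seed = 101)
sim <- generateStudy(cfg, includeMutant = TRUE)

de <- moderatedT(sim$study, "t1")
enriched <- callEnriched(de, fcThreshold = 1.5, fdrThreshold = 0.01)
length(enriched)
#> [1] 38
mean(deGenes(sim$truth)$t1 %in% enriched)
#> [1] 0.925

# over-representation from printed table marginals: a 28-gene
# compartmentalised-ciliogenesis set overlapping a 429-gene list by 23,
# universe 14,075 trusted genes
fisherEnrichment(universe = 14075, k = 23, m = 28, n = 429)
#> EnrichmentResult: k=23 of set m=28, list n=429, universe N=14075
#>   fold = 27   p(Fisher) = 6.47e-31   p(EASE) = 8.32e-29   *

# candidate proneural targets: enriched in wild type, lost in the mutant
scr <- screenTargets(de, moderatedT(sim$study, "t1", genotype = "mutant"))
head(scr[scr$passes_s12, ], 3)
#>   gene_id fc_wt fc_mut ratio passes_s11 passes_s12
#> 1  G01695  3.91  0.601  6.50       TRUE       TRUE
#> 2  G00956  5.43  0.846  6.41       TRUE       TRUE
#> 3  G00867  5.36  1.034  5.19       TRUE       TRUE
```

The first block recovers 92.5% of the genes planted DE at t1 at the 1.5-fold
/ 1% FDR thresholds; the Fisher result reproduces the 27-fold enrichment a
23/28-gene overlap implies at those marginals; the screen ranks genes whose
wild-type enrichment collapses in the mutant — the signature of a gene
acting downstream of the proneural factor.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
model, parameter choices, the synthetic generator's scope, numerical
details (log-space tails, rounding, tie-breaks, degenerate inputs) and
known limitations.
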