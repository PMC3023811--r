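# Accessor generics for the result classes. Slot access from user code is
# discouraged; these are the supported surface.

#' @rdname EnrichmentResult-class
#' @param object an object.
#' @export
setGeneric("overlapCount", function(object) standardGeneric("overlapCount"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("setSize", function(object) standardGeneric("setSize"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("listSize", function(object) standardGeneric("listSize"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("universeSize", function(object) standardGeneric("universeSize"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("foldEnrichment", function(object) standardGeneric("foldEnrichment"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("pFisher", function(object) standardGeneric("pFisher"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("pEase", function(object) standardGeneric("pEase"))
#' @rdname EnrichmentResult-class
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

setMethod("overlapCount", "EnrichmentResult", function(object) object@k)
setMethod("setSize", "EnrichmentResult", function(object) object@m)
setMethod("listSize", "EnrichmentResult", function(object) object@n)
setMethod("universeSize", "EnrichmentResult", function(object) object@N)
setMethod("foldEnrichment", "EnrichmentResult", function(object) object@fold)
setMethod("pFisher", "EnrichmentResult", function(object) object@pFisher)
setMethod("pEase", "EnrichmentResult", function(object) object@pEase)
setMethod("isSignificant", "EnrichmentResult", function(object) object@significant)

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: k=%d of set m=%d, list n=%d, universe N=%d\n",
    object@k, object@m, object@n, object@N))
  cat(sprintf("  fold = %.3g   p(Fisher) = %.3g   p(EASE) = %.3g%s\n",
    object@fold, object@pFisher, object@pEase,
    if (isTRUE(object@significant)) "   *" else ""))
})

#' @rdname ResamplingNull-class
#' @param object an object.
#' @export
setGeneric("observedScore", function(object) standardGeneric("observedScore"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("nullSamples", function(object) standardGeneric("nullSamples"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("nullMean", function(object) standardGeneric("nullMean"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("nullSD", function(object) standardGeneric("nullSD"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("zScore", function(object) standardGeneric("zScore"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("pNormal", function(object) standardGeneric("pNormal"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("pEmpirical", function(object) standardGeneric("pEmpirical"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("enrichmentFactor", function(object) standardGeneric("enrichmentFactor"))
#' @rdname ResamplingNull-class
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))

setMethod("observedScore", "ResamplingNull", function(object) object@observed)
setMethod("nullSamples", "ResamplingNull", function(object) object@samples)
setMethod("nullMean", "ResamplingNull", function(object) object@mu)
setMethod("nullSD", "ResamplingNull", function(object) object@sigma)
setMethod("zScore", "ResamplingNull", function(object) object@z)
setMethod("pNormal", "ResamplingNull", function(object) object@p)
setMethod("pEmpirical", "ResamplingNull", function(object) object@pEmpirical)
setMethod("enrichmentFactor", "ResamplingNull", function(object) object@enrichmentFactor)
setMethod("isDegenerate", "ResamplingNull", function(object) object@degenerate)

setMethod("show", "ResamplingNull", function(object) {
  cat(sprintf("ResamplingNull: %d iterations (seed %d)\n",
              object@nIter, object@seed))
  if (object@degenerate) {
    cat(sprintf("  degenerate null (sigma = 0), observed = %g\n", object@observed))
  } else {
    cat(sprintf("  observed = %g   null mean = %.4g   null SD = %.4g\n",
                object@observed, object@mu, object@sigma))
    cat(sprintf("  z = %.3f   p(normal) = %.3g   p(empirical) = %.3g   enrichment = %.3gx\n",
                object@z, object@p, object@pEmpirical, object@enrichmentFactor))
  }
})

#' @rdname TemporalPartition-class
#' @param object an object.
#' @export
setGeneric("regionSets", function(object) standardGeneric("regionSets"))
#' @rdname TemporalPartition-class
#' @export
setGeneric("regionCounts", function(object) standardGeneric("regionCounts"))
#' @rdname TemporalPartition-class
#' @export
setGeneric("timepointTotals", function(object) standardGeneric("timepointTotals"))

setMethod("regionSets", "TemporalPartition", function(object) object@regionSets)
setMethod("regionCounts", "TemporalPartition", function(object)
  vapply(object@regionSets, length, integer(1)))
setMethod("timepointTotals", "TemporalPartition", function(object) object@totals)

setMethod("show", "TemporalPartition", function(object) {
  cat("TemporalPartition of three gene lists\n")
  cat("  totals:", paste(sprintf("%s=%d", names(object@totals), object@totals),
                         collapse = ", "), "\n")
  cnt <- regionCounts(object)
  for (r in names(cnt)) cat(sprintf("  region %s: %d genes\n", r, cnt[[r]]))
})

#' @rdname SyntheticTruth-class
#' @param object an object.
#' @export
setGeneric("deGenes", function(object) standardGeneric("deGenes"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedSetMembers", function(object) standardGeneric("plantedSetMembers"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedMotifPositions", function(object) standardGeneric("plantedMotifPositions"))
#' @rdname SyntheticTruth-class
#' @export
setGeneric("mutantDependentGenes", function(object) standardGeneric("mutantDependentGenes"))

setMethod("deGenes", "SyntheticTruth", function(object) object@deGenes)
setMethod("plantedSetMembers", "SyntheticTruth", function(object) object@setMembers)
setMethod("plantedMotifPositions", "SyntheticTruth", function(object) object@motifPositions)
setMethod("mutantDependentGenes", "SyntheticTruth", function(object) object@mutantDependentGenes)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth\n")
  if (length(object@deGenes))
    cat("  planted DE:", paste(sprintf("%s=%d", names(object@deGenes),
        vapply(object@deGenes, length, integer(1))), collapse = ", "), "\n")
  if (length(object@setMembers))
    cat("  planted sets:", paste(names(object@setMembers), collapse = ", "), "\n")
  if (length(object@motifPositions))
    cat(sprintf("  genes with planted motifs: %d\n",
        sum(vapply(object@motifPositions, nrow, integer(1)) > 0)))
  if (length(object@mutantDependentGenes))
    cat(sprintf("  mutant-dependent genes: %d\n",
        length(object@mutantDependentGenes)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  %d genes, %d replicates, timepoints: %s\n", object@nGenes,
      object@nReplicates, paste(object@timepoints, collapse = ", ")))
  cat(sprintf("  onset fractions: %s (%s)\n",
      paste(object@onsetFractions, collapse = ", "),
      if (object@transientOnset) "transient" else "cumulative"))
  cat(sprintf("  effect %.2f log2, noise SD %.2f, heterogeneity %.2f\n",
      object@effectSize, object@noiseSd, object@varianceHeterogeneity))
  cat(sprintf("  promoters: %d bp, motif %s (plant %.2f, background %.3f/kb)\n",
      object@promoterLength, object@motifPattern, object@motifPlantRate,
      object@backgroundMotifRate))
  cat(sprintf("  seed %d\n", object@seed))
})
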