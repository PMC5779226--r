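#' @rdname generateTruth
#' @export
setGeneric("generateTruth", function(config, ...) standardGeneric("generateTruth"))

#' @rdname simulateAbundance
#' @export
setGeneric("simulateAbundance", function(truth, ...) standardGeneric("simulateAbundance"))

#' @rdname simulateCounts
#' @export
setGeneric("simulateCounts", function(truth, abundances, ...) standardGeneric("simulateCounts"))

#' @rdname computeFPKM
#' @export
setGeneric("computeFPKM", function(x, ...) standardGeneric("computeFPKM"))

#' @rdname spikeinNormalize
#' @export
setGeneric("spikeinNormalize", function(x, counts, ...) standardGeneric("spikeinNormalize"))

#' @rdname filterExpressed
#' @export
setGeneric("filterExpressed", function(x, ...) standardGeneric("filterExpressed"))

#' @rdname bindingScore
#' @export
setGeneric("bindingScore", function(x, ...) standardGeneric("bindingScore"))

#' @rdname relativeEnrichment
#' @export
setGeneric("relativeEnrichment", function(x, ...) standardGeneric("relativeEnrichment"))

#' @rdname bindingChange
#' @export
setGeneric("bindingChange", function(x, ...) standardGeneric("bindingChange"))

#' @rdname rnaFoldChange
#' @export
setGeneric("rnaFoldChange", function(x, ...) standardGeneric("rnaFoldChange"))

#' @rdname timepointCorrelationMatrix
#' @export
setGeneric("timepointCorrelationMatrix", function(x, ...) standardGeneric("timepointCorrelationMatrix"))

#' @rdname abundanceComparison
#' @export
setGeneric("abundanceComparison", function(x, ...) standardGeneric("abundanceComparison"))

#' Is this expression matrix spike-in normalized?
#'
#' @param x an [FPKMSet].
#' @return logical scalar.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @describeIn isNormalized the `metadata(x)$normalized` flag.
#' @export
setMethod("isNormalized", "FPKMSet", function(x) isTRUE(metadata(x)$normalized))

#' Accessors for CorrelationResult
#'
#' @param object a [CorrelationResult].
#' @return `corRho` the rank correlation; `corP` the (floored) two-sided
#'   p-value; `corN` the number of pairs used.
#' @aliases corP corN
#' @export
setGeneric("corRho", function(object) standardGeneric("corRho"))

#' @rdname corRho
#' @export
setGeneric("corP", function(object) standardGeneric("corP"))

#' @rdname corRho
#' @export
setGeneric("corN", function(object) standardGeneric("corN"))

setMethod("corRho", "CorrelationResult", function(object) object@rho)
setMethod("corP", "CorrelationResult", function(object) object@pValue)
setMethod("corN", "CorrelationResult", function(object) object@n)

setMethod("show", "CorrelationResult", function(object) {
  lab <- if (object@method == "partial_spearman")
    sprintf("corrected r_s (given %s)", object@covariate) else "r_s"
  cat(sprintf("%s = %.3f, %s, n = %d\n", lab, object@rho,
              .formatP(object@pValue, object@pFloored), object@n))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes +", object@nSpikein,
      "spike-ins,", length(object@timePoints), "time points,",
      object@nReplicates, "replicate(s)\n")
  cat("  proteins:", paste(object@proteins, collapse = ", "),
      "| dispersion:", object@dispersion,
      "| seed:", object@seed, "\n")
  cat("  capture efficiency:",
      paste(format(object@captureEfficiency), collapse = " "), "\n")
  cat("  decay coupling:",
      paste(format(object@decayCoupling), collapse = " "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@geneId), "genes (",
      sum(object@spikein), "spike-in ),",
      ncol(object@logAffinity), "proteins,",
      ncol(object@decayRate), "decay intervals\n")
})

setMethod("show", "StratifiedResult", function(object) {
  cat(sprintf("StratifiedResult: %d x %d %s bins over %d genes; %d adjacent-bin K-S tests\n",
              object@nPrimary, object@nSecondary,
              if (object@nested) "nested" else "global",
              nrow(object@assignment), nrow(object@ksTests)))
})

#' Accessors for SyntheticTruth
#'
#' @param object a [SyntheticTruth].
#' @return `truthGenes` the gene ids; `truthAffinity` the genes x
#'   proteins natural-log affinity matrix; `truthDecayRate` the genes x
#'   intervals decay-rate matrix; `truthCovariates` a data.frame of
#'   gene_id, tail_length (nt) and te (log2) for target genes;
#'   `isSpikein` the spike-in flag.
#' @aliases truthAffinity truthDecayRate truthCovariates isSpikein
#' @export
setGeneric("truthGenes", function(object) standardGeneric("truthGenes"))

#' @rdname truthGenes
#' @export
setGeneric("truthAffinity", function(object) standardGeneric("truthAffinity"))

#' @rdname truthGenes
#' @export
setGeneric("truthDecayRate", function(object) standardGeneric("truthDecayRate"))

#' @rdname truthGenes
#' @export
setGeneric("truthCovariates", function(object) standardGeneric("truthCovariates"))

#' @rdname truthGenes
#' @export
setGeneric("isSpikein", function(object) standardGeneric("isSpikein"))

setMethod("truthGenes", "SyntheticTruth", function(object) object@geneId)
setMethod("truthAffinity", "SyntheticTruth", function(object) {
  m <- object@logAffinity
  rownames(m) <- object@geneId
  m
})
setMethod("truthDecayRate", "SyntheticTruth", function(object) {
  m <- object@decayRate
  rownames(m) <- object@geneId
  m
})
setMethod("truthCovariates", "SyntheticTruth", function(object) {
  keep <- !object@spikein
  data.frame(gene_id = object@geneId[keep],
             tail_length = object@tailLength[keep],
             te = object@te[keep])
})
setMethod("isSpikein", "SyntheticTruth", function(object) {
  stats::setNames(object@spikein, object@geneId)
})
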