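#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.SPECIES_LEVELS <- c("target", "spikein")

#' Container for gene-level RIP-seq read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one integer
#' \code{counts} assay with genes in rows and libraries in columns.
#' \code{rowData} carries \code{species} (\code{"target"} or
#' \code{"spikein"}, flagging reads that map to the spiked-in foreign
#' species) and \code{length_nt} (gene model length in nucleotides);
#' \code{colData} carries \code{fraction} (\code{"input"} or \code{"IP"}),
#' \code{protein} (the immunoprecipitated protein, \code{NA} for inputs),
#' \code{time_point} and \code{replicate}.
#'
#' @seealso [RIPCountSet()] for the constructor, [readCountTable()] to
#'   import from TSV, [computeFPKM()] for the first quantification step.
#' @export
setClass("RIPCountSet", contains = "SummarizedExperiment")

setValidity("RIPCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  if (!all(c("species", "length_nt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'species' and 'length_nt'")
  cd <- colData(object)
  if (!all(c("fraction", "time_point") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'fraction' and 'time_point'")
  if (length(msg)) return(msg)
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids in rownames")
  if (!all(rd$species %in% .SPECIES_LEVELS))
    msg <- c(msg, sprintf("species must be one of: %s",
                          paste(.SPECIES_LEVELS, collapse = ", ")))
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "negative counts")
  tot <- colSums(cnt[rd$species == "target", , drop = FALSE])
  if (any(tot <= 0))
    msg <- c(msg, sprintf("library with no target-species counts: %s",
                          paste(colnames(object)[tot <= 0], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-gene FPKM values per library
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one \code{fpkm}
#' assay, sharing row/column annotation with the [RIPCountSet] it was
#' derived from. \code{metadata(x)$normalized} records whether spike-in
#' scale factors have been applied to the input libraries (see
#' [spikeinNormalize()]); several downstream steps demand one state or the
#' other, because binding divides by the \emph{unnormalized} input while
#' cross-time abundance comparisons are only meaningful after spike-in
#' scaling.
#'
#' @seealso [computeFPKM()], [spikeinNormalize()], [isNormalized()]
#' @export
setClass("FPKMSet", contains = "SummarizedExperiment")

setValidity("FPKMSet", function(object) {
  msg <- character()
  if (!"fpkm" %in% assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    f <- assay(object, "fpkm")
    if (any(!is.finite(f)) || any(f < 0))
      msg <- c(msg, "FPKM values must be finite and non-negative")
  }
  if (!is.logical(metadata(object)$normalized))
    msg <- c(msg, "metadata 'normalized' flag (logical) is required")
  if (length(msg)) msg else TRUE
})

#' Relative binding per gene, protein and time point
#'
#' Holds the study's central statistic: per-gene log2 relative binding,
#' defined as log2(IP FPKM / unnormalized input FPKM) median-centered
#' within each (protein, time point) library pair, so that the median
#' log2 binding of all retained transcripts is 0. One assay
#' \code{log2binding}; columns are (protein, time point) combinations
#' described in \code{colData}.
#'
#' @seealso [bindingScore()], [relativeEnrichment()], [bindingChange()]
#' @export
setClass("BindingSet", contains = "SummarizedExperiment")

setValidity("BindingSet", function(object) {
  msg <- character()
  if (!"log2binding" %in% assayNames(object))
    msg <- c(msg, "assay 'log2binding' is required")
  cd <- colData(object)
  if (!all(c("protein", "time_point") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'protein' and 'time_point'")
  if (length(msg)) return(msg)
  b <- assay(object, "log2binding")
  med <- apply(b, 2, stats::median, na.rm = TRUE)
  # tolerance admits round-tripping through 6-significant-digit TSV
  if (any(abs(med) > 1e-4, na.rm = TRUE))
    msg <- c(msg, "log2 binding must be median-centered per column")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic RIP-seq experiment generator
#'
#' Bundles every tunable of the generative model: the design (genes, time
#' points, proteins, replicates), sequencing depths, negative-binomial
#' dispersion, the target Spearman correlation structure among the latent
#' per-gene variables (affinity for each protein, mean poly(A)-tail
#' length, translational efficiency), the per-time-point IP capture
#' efficiency (emulating the >10-fold decline of the immunoprecipitated
#' proteins across the MZT), and the interval-wise coupling between
#' ME31B affinity and mRNA decay that produces the regime switch.
#'
#' Use [simulationConfig()] to construct; all defaults encode the study
#' conditions the generator is meant to emulate.
#'
#' @slot nGenes number of target-species genes.
#' @slot timePoints ordered time-point labels.
#' @slot proteins labels of the two immunoprecipitated proteins; the
#'   first is the one coupled to decay (ME31B in the study).
#' @slot depthTarget expected target-species reads per library.
#' @slot depthSpikein expected spike-in reads per input library at the
#'   first time point.
#' @slot dispersion negative-binomial dispersion (\code{size = 1/dispersion}).
#' @slot latentCorrelations 4x4 target Spearman matrix over
#'   (protein1 affinity, protein2 affinity, tail length, TE).
#' @slot captureEfficiency per-time-point multiplier on IP yield, in
#'   (0, 1], non-increasing.
#' @slot decayCoupling per-interval coefficient linking binding to decay;
#'   negative values mean highly bound transcripts decay faster.
#' @slot decayBase baseline of the softplus decay-rate model.
#' @slot decayGeneSD gene-level spread of intrinsic mRNA stability.
#' @slot affinitySD natural-log SD of IP affinities.
#' @slot tailMeanLog,tailSDLog lognormal parameters of tail length (nt).
#' @slot teSD SD of translational efficiency on the log2 scale.
#' @slot abundanceMeanLog,abundanceSDLog lognormal parameters of initial
#'   abundance.
#' @slot lengthMeanLog,lengthSDLog lognormal parameters of gene length.
#' @slot nSpikein number of spike-in genes.
#' @slot ipSpikein whether IP libraries also receive spike-in reads
#'   (default \code{FALSE}: only inputs are spiked).
#' @slot nReplicates libraries per condition.
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    timePoints = "character",
    proteins = "character",
    depthTarget = "numeric",
    depthSpikein = "numeric",
    dispersion = "numeric",
    latentCorrelations = "matrix",
    captureEfficiency = "numeric",
    decayCoupling = "numeric",
    decayBase = "numeric",
    decayGeneSD = "numeric",
    affinitySD = "numeric",
    tailMeanLog = "numeric",
    tailSDLog = "numeric",
    teSD = "numeric",
    abundanceMeanLog = "numeric",
    abundanceSDLog = "numeric",
    lengthMeanLog = "numeric",
    lengthSDLog = "numeric",
    nSpikein = "integer",
    ipSpikein = "logical",
    nReplicates = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@timePoints) < 1L || anyDuplicated(object@timePoints))
    msg <- c(msg, "timePoints must be non-empty and unique")
  if (length(object@proteins) != 2L || anyDuplicated(object@proteins))
    msg <- c(msg, "exactly two distinct protein labels are required")
  if (any(c(object@depthTarget, object@depthSpikein) <= 0))
    msg <- c(msg, "sequencing depths must be strictly positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  S <- object@latentCorrelations
  if (!identical(dim(S), c(4L, 4L)) ||
      max(abs(S - t(S))) > 1e-12 ||
      max(abs(diag(S) - 1)) > 1e-12)
    msg <- c(msg, "latentCorrelations must be a symmetric 4x4 matrix with unit diagonal")
  ce <- object@captureEfficiency
  if (length(ce) != length(object@timePoints) ||
      any(ce <= 0) || any(ce > 1))
    msg <- c(msg, "captureEfficiency must lie in (0, 1], one value per time point")
  else if (any(diff(ce) > 1e-12))
    msg <- c(msg, "captureEfficiency must be non-increasing across time points")
  if (length(object@decayCoupling) != max(length(object@timePoints) - 1L, 0L))
    msg <- c(msg, "decayCoupling needs one value per adjacent time-point interval")
  if (object@nSpikein < 1L)
    msg <- c(msg, "at least one spike-in gene is required")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Planted per-gene truth of a synthetic experiment
#'
#' The latent parameters the generator drew for each gene, kept so that
#' pipeline estimates can be compared against what was planted: log IP
#' affinities per protein, mean poly(A)-tail length, translational
#' efficiency, initial abundance, per-interval decay rates, gene length,
#' and the spike-in flag. Spike-in genes have zero affinity, zero decay
#' and no covariates.
#'
#' @slot geneId gene identifiers.
#' @slot spikein logical spike-in flag.
#' @slot lengthNt gene lengths (nt).
#' @slot logAffinity genes x proteins matrix of natural-log IP affinities.
#' @slot tailLength mean poly(A)-tail length (nt); NA for spike-ins.
#' @slot te translational efficiency (log2); NA for spike-ins.
#' @slot initialAbundance abundance at the first time point (arbitrary units).
#' @slot decayRate genes x intervals matrix of first-order decay rates (/hr).
#' @slot config the [SimulationConfig] used.
#' @export
setClass("SyntheticTruth",
  representation(
    geneId = "character",
    spikein = "logical",
    lengthNt = "numeric",
    logAffinity = "matrix",
    tailLength = "numeric",
    te = "numeric",
    initialAbundance = "numeric",
    decayRate = "matrix",
    config = "SimulationConfig"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  n <- length(object@geneId)
  if (anyDuplicated(object@geneId)) msg <- c(msg, "duplicate gene ids")
  if (length(object@spikein) != n || length(object@lengthNt) != n ||
      nrow(object@logAffinity) != n || nrow(object@decayRate) != n)
    msg <- c(msg, "per-gene slots must have one entry per gene")
  if (sum(object@spikein) != object@config@nSpikein)
    msg <- c(msg, "number of flagged spike-in genes must match the config")
  sp <- object@spikein
  if (any(object@logAffinity[sp, ] != 0))
    msg <- c(msg, "spike-in genes must have zero IP affinity")
  if (any(object@decayRate[sp, ] != 0))
    msg <- c(msg, "spike-in genes must not decay")
  if (any(object@lengthNt <= 0)) msg <- c(msg, "gene lengths must be positive")
  if (any(object@initialAbundance <= 0))
    msg <- c(msg, "initial abundances must be positive")
  if (any(object@decayRate < 0)) msg <- c(msg, "decay rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A Spearman or partial-Spearman correlation with its test
#'
#' @slot rho the rank correlation, in [-1, 1].
#' @slot pValue two-sided p-value, floored at 1e-15 (the study's
#'   reporting convention prints anything smaller as "p < 10^-15").
#' @slot pFloored whether the floor was hit.
#' @slot n number of gene pairs used.
#' @slot method "spearman" or "partial_spearman".
#' @slot covariate name of the variable corrected for, or NA.
#' @export
setClass("CorrelationResult",
  representation(rho = "numeric", pValue = "numeric", pFloored = "logical",
                 n = "integer", method = "character", covariate = "character")
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@rho) > 1 + 1e-12) msg <- c(msg, "|rho| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Nested quantile stratification of an outcome
#'
#' Result of [stratifiedBins()]: genes are ranked into near-equal-size
#' primary quantile bins (quintiles of ME31B binding in the study), then
#' into secondary bins (tail-length tertiles) within each primary bin,
#' and the outcome distribution (translational efficiency) is summarized
#' per cell, with two-sample Kolmogorov-Smirnov tests between
#' corresponding cells of adjacent primary bins.
#'
#' @slot assignment data.frame: gene_id, primaryBin, secondaryBin.
#' @slot summaries data.frame of per-cell box-plot statistics (median,
#'   quartiles, Tukey whiskers = range excluding points beyond 1.5 IQR).
#' @slot ksTests data.frame of adjacent-primary-bin K-S statistics and p.
#' @slot nested whether secondary bins were computed within each primary
#'   bin (TRUE) or globally.
#' @slot nPrimary,nSecondary bin counts.
#' @export
setClass("StratifiedResult",
  representation(assignment = "data.frame", summaries = "data.frame",
                 ksTests = "data.frame", nested = "logical",
                 nPrimary = "integer", nSecondary = "integer")
)
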