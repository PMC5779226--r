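#' Default latent Spearman correlation structure
#'
#' Target Spearman correlations among the latent per-gene variables, in
#' the order (protein 1 affinity, protein 2 affinity, tail length, TE).
#' The defaults encode the associations reported for 0-1 hr embryos:
#' ME31B and PABP binding strongly co-vary (0.62), ME31B binding is
#' anti-correlated with poly(A)-tail length (-0.38) and translational
#' efficiency (-0.29), tail length and TE are positively related (0.38),
#' and PABP binding is essentially independent of tail length. The
#' PABP-TE entry is not constrained by the study and is set near the
#' product of the two paths through ME31B.
#'
#' @param proteins two protein labels used for the dimnames.
#' @return symmetric 4x4 matrix with unit diagonal.
#' @export
defaultLatentCorrelations <- function(proteins = c("ME31B", "PABP")) {
  S <- matrix(c(
     1.00,  0.62, -0.38, -0.29,
     0.62,  1.00,  0.00, -0.18,
    -0.38,  0.00,  1.00,  0.38,
    -0.29, -0.18,  0.38,  1.00), 4, 4, byrow = TRUE)
  dimnames(S) <- rep(list(c(proteins, "tail_length", "te")), 2)
  S
}

#' Construct a simulation configuration
#'
#' Builds a validated [SimulationConfig]. The defaults define the
#' emulated study: 5000 target genes plus 500 spike-in genes over five
#' one-hour time points, paired input and IP libraries for ME31B and
#' PABP, one replicate per condition, a constant foreign-species spike
#' present in input libraries only, IP capture efficiency declining more
#' than 10-fold across the time course, and binding-coupled decay that is
#' switched off in the first interval and on thereafter (the
#' repression-to-decay regime switch).
#'
#' The decay model for target gene g in interval i is
#' \deqn{rate_i(g) = softplus(base_i - coupling_i z_g + sd\, u_{gi})}
#' where \eqn{z_g} is the standardized ME31B affinity and \eqn{u_{gi}}
#' a standard-normal gene effect, drawn independently per interval,
#' encoding intrinsic stability differences (basal pre-MZT turnover and
#' MZT-activated decay are driven by different machinery, so their
#' gene-level heterogeneity is modeled as independent). Negative
#' coupling makes highly bound transcripts decay faster, and coupling 0
#' makes decay independent of binding; the lower first-interval
#' baseline reflects the relative stability of maternal transcripts
#' before zygotic genome activation.
#'
#' @param nGenes number of target genes.
#' @param timePoints ordered labels of the sampled developmental windows.
#' @param proteins the two immunoprecipitated proteins (first one drives
#'   decay coupling).
#' @param depthTarget expected target-species reads per library.
#' @param depthSpikein expected spike-in reads per input library at the
#'   first time point.
#' @param dispersion negative-binomial dispersion; 0 gives Poisson counts.
#' @param latentCorrelations target Spearman matrix, see
#'   [defaultLatentCorrelations()].
#' @param captureEfficiency non-increasing per-time-point IP yield in (0,1].
#' @param decayCoupling per-interval binding-to-decay coefficients.
#' @param decayBase per-interval baseline of the softplus decay model
#'   (recycled; natural-log rate per hour).
#' @param decayGeneSD gene-level spread of intrinsic mRNA stability on
#'   the softplus argument scale.
#' @param affinitySD natural-log SD of IP affinities.
#' @param tailMeanLog,tailSDLog lognormal parameters for tail length (nt).
#' @param teSD SD of TE (log2).
#' @param abundanceMeanLog,abundanceSDLog lognormal parameters for
#'   initial abundance.
#' @param lengthMeanLog,lengthSDLog lognormal parameters for gene length.
#' @param nSpikein number of spike-in genes.
#' @param ipSpikein spike IP libraries too? (the study spikes inputs only).
#' @param nReplicates libraries per condition.
#' @param seed integer seed (< 2^30 so derived stream seeds stay valid).
#' @return a [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(nGenes = 200, nSpikein = 20, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nGenes = 5000L,
                             timePoints = c("0-1h", "1-2h", "2-3h", "3-4h", "4-5h"),
                             proteins = c("ME31B", "PABP"),
                             depthTarget = 4e7,
                             depthSpikein = 2e6,
                             dispersion = 0.005,
                             latentCorrelations = defaultLatentCorrelations(proteins),
                             captureEfficiency = .defaultCapture(length(timePoints)),
                             decayCoupling = c(0, rep(-1, max(length(timePoints) - 2L, 0L))),
                             decayBase = c(-1.5, rep(-1, max(length(timePoints) - 2L, 0L))),
                             decayGeneSD = 1.5,
                             affinitySD = 1,
                             tailMeanLog = log(60),
                             tailSDLog = 0.4,
                             teSD = 1,
                             abundanceMeanLog = 3.5,
                             abundanceSDLog = 1.2,
                             lengthMeanLog = log(1500),
                             lengthSDLog = 0.5,
                             nSpikein = 500L,
                             ipSpikein = FALSE,
                             nReplicates = 1L,
                             seed = 1L) {
  if (seed >= 2^30) stop("seed must be below 2^30", call. = FALSE)
  new("SimulationConfig",
      nGenes = as.integer(nGenes), timePoints = as.character(timePoints),
      proteins = as.character(proteins),
      depthTarget = depthTarget, depthSpikein = depthSpikein,
      dispersion = dispersion, latentCorrelations = latentCorrelations,
      captureEfficiency = captureEfficiency,
      decayCoupling = decayCoupling, decayBase = decayBase,
      decayGeneSD = decayGeneSD, affinitySD = affinitySD,
      tailMeanLog = tailMeanLog, tailSDLog = tailSDLog, teSD = teSD,
      abundanceMeanLog = abundanceMeanLog, abundanceSDLog = abundanceSDLog,
      lengthMeanLog = lengthMeanLog, lengthSDLog = lengthSDLog,
      nSpikein = as.integer(nSpikein), ipSpikein = ipSpikein,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

# >10-fold decline of IP capture across the time course, interpolated
# geometrically for designs with other than five time points.
.defaultCapture <- function(nT) {
  if (nT == 1L) return(1)
  signif(exp(seq(0, log(0.08), length.out = nT)), 3)
}

#' Convert a target Spearman matrix to the Gaussian copula scale
#'
#' Uses the exact bivariate-normal relation
#' \eqn{\rho_{pearson} = 2 \sin(\pi \rho_{spearman} / 6)} so that latent
#' draws from the copula reproduce the requested Spearman correlations.
#'
#' @param S symmetric Spearman correlation matrix with unit diagonal.
#' @return the corresponding Pearson correlation matrix; errors if the
#'   converted matrix is not positive semi-definite, naming the offending
#'   eigenvalue.
#' @export
spearmanToPearson <- function(S) {
  P <- 2 * sin(pi * S / 6)
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf(
      "latent correlation matrix is not positive semi-definite after copula conversion (eigenvalue %.6g)",
      min(ev)), call. = FALSE)
  P
}

#' Draw the planted per-gene truth
#'
#' Samples latent gene parameters from a Gaussian copula whose
#' correlation matrix is the copula conversion of the configured target
#' Spearman matrix, then maps the marginals to their stated scales:
#' affinities to a natural-log-normal scale, tail length lognormal,
#' TE normal on log2, with independent lognormal initial abundances and
#' gene lengths. Decay rates follow the softplus model of
#' [simulationConfig()], with the first-interval coupling of 0 making
#' decay binding-independent there. Spike-in genes form a separate block
#' with zero affinity, constant abundance and no covariates.
#'
#' @param config a [SimulationConfig].
#' @param ... unused.
#' @return a [SyntheticTruth].
#' @examples
#' truth <- generateTruth(simulationConfig(nGenes = 100, nSpikein = 10, seed = 7))
#' truth
#' @export
setMethod("generateTruth", "SimulationConfig", function(config, ...) {
  validObject(config)
  P <- spearmanToPearson(config@latentCorrelations)
  n <- config@nGenes
  nS <- config@nSpikein
  nInt <- length(config@timePoints) - 1L

  .withSeed(config@seed, {
    # chol of PSD matrix; jitter the (rare) semi-definite boundary case
    L <- tryCatch(chol(P), error = function(e) chol(P + 1e-10 * diag(4)))
    Z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% L
    logAff <- cbind(config@affinitySD * Z[, 1L], config@affinitySD * Z[, 2L])
    colnames(logAff) <- config@proteins
    tail <- exp(config@tailMeanLog + config@tailSDLog * Z[, 3L])
    te <- config@teSD * Z[, 4L]
    abundance <- stats::rlnorm(n, config@abundanceMeanLog, config@abundanceSDLog)
    len <- pmax(round(stats::rlnorm(n, config@lengthMeanLog, config@lengthSDLog)), 200)
    base <- rep_len(config@decayBase, max(nInt, 1L))
    rate <- matrix(0, n, max(nInt, 0L))
    for (i in seq_len(nInt)) {
      u <- stats::rnorm(n)  # per-interval intrinsic stability effect
      rate[, i] <- .softplus(base[i] - config@decayCoupling[i] * Z[, 1L] +
                               config@decayGeneSD * u)
    }

    spikeAbund <- stats::rlnorm(nS, config@abundanceMeanLog, config@abundanceSDLog)
    spikeLen <- pmax(round(stats::rlnorm(nS, config@lengthMeanLog, config@lengthSDLog)), 200)

    ids <- c(sprintf("g%05d", seq_len(n)), sprintf("spike%04d", seq_len(nS)))
    zeroes <- matrix(0, nS, ncol(logAff), dimnames = list(NULL, config@proteins))
    new("SyntheticTruth",
        geneId = ids,
        spikein = c(rep(FALSE, n), rep(TRUE, nS)),
        lengthNt = c(len, spikeLen),
        logAffinity = rbind(logAff, zeroes),
        tailLength = c(tail, rep(NA_real_, nS)),
        te = c(te, rep(NA_real_, nS)),
        initialAbundance = c(abundance, spikeAbund),
        decayRate = rbind(rate, matrix(0, nS, max(nInt, 0L))),
        config = config)
  })
})

#' Propagate abundances through the decay time course
#'
#' Applies the planted first-order decay gene-by-gene:
#' \eqn{A_{t+1} = A_t e^{-rate_t}}. Spike-in genes have zero decay rates
#' and therefore constant abundance, mirroring the fixed amount of
#' foreign RNA added to every sample.
#'
#' @param truth a [SyntheticTruth].
#' @param ... unused.
#' @return positive matrix, genes x time points.
#' @export
setMethod("simulateAbundance", "SyntheticTruth", function(truth, ...) {
  tps <- truth@config@timePoints
  A <- matrix(0, length(truth@geneId), length(tps),
              dimnames = list(truth@geneId, tps))
  A[, 1L] <- truth@initialAbundance
  for (t in seq_len(length(tps) - 1L))
    A[, t + 1L] <- A[, t] * exp(-truth@decayRate[, t])
  A
})

# Expected counts per (gene, library). Input libraries sequence the
# combined target + spike pool at constant total depth, so the spike-in
# share grows as the maternal transcriptome is degraded -- exactly the
# signal the spike-in normalization exploits. IP libraries scale with
# capture efficiency and the current pool, anchored so that an
# efficiency-1 library at t = 1 yields depthTarget reads in expectation.
.expectedLibraryMeans <- function(truth, abundances, config) {
  tgt <- !truth@spikein
  len <- truth@lengthNt
  tps <- config@timePoints
  nRep <- config@nReplicates

  T1 <- sum(abundances[tgt, 1L] * len[tgt])
  spikePoolRaw <- sum(abundances[!tgt, 1L] * len[!tgt])
  kappa <- (config@depthSpikein / config@depthTarget) * T1 / spikePoolRaw
  D <- config@depthTarget + config@depthSpikein

  libs <- character(0)
  mus <- list()
  for (t in seq_along(tps)) {
    w <- abundances[, t] * len
    w[!tgt] <- w[!tgt] * kappa
    muIn <- D * w / sum(w)
    for (r in seq_len(nRep)) {
      nm <- .libraryName("input", NA, tps[t], r, nRep)
      libs <- c(libs, nm); mus[[nm]] <- muIn
    }
  }
  for (p in config@proteins) {
    wRef <- abundances[tgt, 1L] * len[tgt] * exp(truth@logAffinity[tgt, p])
    K <- config@depthTarget / (sum(wRef) * config@captureEfficiency[1L])
    for (t in seq_along(tps)) {
      mu <- numeric(length(len))
      mu[tgt] <- K * config@captureEfficiency[t] *
        abundances[tgt, t] * len[tgt] * exp(truth@logAffinity[tgt, p])
      if (config@ipSpikein) {
        w <- abundances[!tgt, t] * len[!tgt]
        mu[!tgt] <- config@depthSpikein * w / sum(w)
      }
      for (r in seq_len(nRep)) {
        nm <- .libraryName("IP", p, tps[t], r, nRep)
        libs <- c(libs, nm); mus[[nm]] <- mu
      }
    }
  }
  out <- do.call(cbind, mus[libs])
  dimnames(out) <- list(truth@geneId, libs)
  out
}

#' Draw negative-binomial RIP-seq count libraries
#'
#' Given the planted truth and the abundance time course, draws one
#' input library and one IP library per protein per time point (times
#' the configured replicate number). Input expected counts are
#' proportional to abundance times gene length within a pool that also
#' contains the constant spike-in block; IP expected counts additionally
#' carry the gene's IP affinity and the time point's capture efficiency,
#' so halving the capture efficiency halves the expected total IP yield
#' without touching per-gene binding ranks. Counts are negative binomial
#' with the configured dispersion (Poisson when dispersion is 0).
#'
#' @param truth a [SyntheticTruth].
#' @param abundances matrix from [simulateAbundance()].
#' @param ... unused.
#' @return a [RIPCountSet].
#' @export
setMethod("simulateCounts", "SyntheticTruth", function(truth, abundances, ...) {
  config <- truth@config
  stopifnot(all(abundances > 0))
  mu <- .expectedLibraryMeans(truth, abundances, config)
  if (any(colSums(mu) <= 0))
    stop("zero total expected counts in library: ",
         paste(colnames(mu)[colSums(mu) <= 0], collapse = ", "), call. = FALSE)

  counts <- .withSeed(config@seed + 1L, {
    k <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    for (j in seq_len(ncol(mu))) {
      m <- mu[, j]
      draw <- if (config@dispersion < 1e-12) stats::rpois(length(m), m)
              else stats::rnbinom(length(m), mu = m, size = 1 / config@dispersion)
      draw[m == 0] <- 0L
      k[, j] <- as.integer(draw)
    }
    storage.mode(k) <- "integer"
    k
  })

  RIPCountSet(counts = counts,
              species = ifelse(truth@spikein, "spikein", "target"),
              lengthNt = truth@lengthNt)
})

#' Construct a RIPCountSet from a count matrix
#'
#' @param counts integer matrix, genes x libraries; column names must
#'   follow \code{<protein|input>_<timepoint>[_rep<k>]}.
#' @param species per-gene "target"/"spikein" tags.
#' @param lengthNt per-gene lengths in nucleotides.
#' @return a validated [RIPCountSet]; library roles are parsed from the
#'   column names into \code{colData}.
#' @export
RIPCountSet <- function(counts, species, lengthNt) {
  cd <- .parseLibraryName(colnames(counts))
  tps <- unique(cd$time_point)
  cd$time_point <- factor(cd$time_point, levels = tps)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(species = species, length_nt = lengthNt),
    colData = DataFrame(cd))
  new("RIPCountSet", se)
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: truth, abundance time course, and count
#' libraries in one call, all driven by the seed in `config`.
#'
#' @param config a [SimulationConfig].
#' @return list with elements `truth` ([SyntheticTruth]), `abundances`
#'   (matrix) and `counts` ([RIPCountSet]).
#' @examples
#' sim <- simulateRIP(simulationConfig(nGenes = 150, nSpikein = 15, seed = 3))
#' sim$counts
#' @export
simulateRIP <- function(config) {
  truth <- generateTruth(config)
  abundances <- simulateAbundance(truth)
  counts <- simulateCounts(truth, abundances)
  list(truth = truth, abundances = abundances, counts = counts)
}
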