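# Recognized run-configuration keys and their parsers. Unknown keys in a
# config file are an error, preventing silently ignored typos.
.CONFIG_KEYS <- list(
  counts = "path", lengths = "path", covariates = "path", targets = "path",
  outdir = "character",
  fpkm_threshold = "numeric", filter_mode = "character",
  nested_tertiles = "logical", residualize = "character",
  replicate_mode = "character", benchmark_gene = "character",
  seed = "integer", n_genes = "integer", n_spikein = "integer",
  depth_target = "numeric", depth_spikein = "numeric",
  dispersion = "numeric", n_replicates = "integer",
  time_points = "character_vector", proteins = "character_vector"
)

.CONFIG_DEFAULTS <- list(
  fpkm_threshold = 0.5, filter_mode = "all_timepoints",
  nested_tertiles = TRUE, residualize = "rank", replicate_mode = "average",
  seed = 1L, n_genes = 5000L, n_spikein = 500L,
  depth_target = 2e7, depth_spikein = 1e6, dispersion = 0.01,
  n_replicates = 1L,
  time_points = c("0-1h", "1-2h", "2-3h", "3-4h", "4-5h"),
  proteins = c("ME31B", "PABP")
)

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys
#' are rejected, path-valued keys must point to existing files, and
#' every omitted key falls back to a documented default (see
#' [defaultRunConfig()]). Comma-separated values are allowed for
#' `time_points` and `proteins`.
#'
#' @param path config file.
#' @return named list with class `ripbind_config`.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- .CONFIG_DEFAULTS
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    type <- .CONFIG_KEYS[[key]]
    if (is.null(type))
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    cfg[[key]] <- switch(type,
      path = {
        if (!file.exists(val))
          stop("config key '", key, "' points to a missing file: ", val,
               call. = FALSE)
        val
      },
      character = val,
      character_vector = trimws(strsplit(val, ",")[[1L]]),
      numeric = as.numeric(val),
      integer = as.integer(val),
      logical = as.logical(val))
    if (type %in% c("numeric", "integer", "logical") && is.na(cfg[[key]]))
      stop("could not parse value for config key '", key, "': ", val,
           call. = FALSE)
  }
  structure(cfg, class = "ripbind_config")
}

#' @rdname readRunConfig
#' @export
defaultRunConfig <- function() structure(.CONFIG_DEFAULTS, class = "ripbind_config")

.runMetadata <- function(cfg, stage) {
  cfgJson <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  on.exit(unlink(tmp))
  list(stage = stage,
       package_version = as.character(utils::packageVersion("ripbind")),
       seed = cfg$seed,
       config = unclass(cfg),
       config_md5 = unname(tools::md5sum(tmp)))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.artifact <- function(outdir, name) file.path(outdir, name)

.needArtifact <- function(outdir, name, stage) {
  p <- .artifact(outdir, name)
  if (!file.exists(p))
    stop("stage '", stage, "' needs missing artifact: ", p,
         " (run the upstream stage first)", call. = FALSE)
  p
}

#' Run the simulate / quantify / associate / dynamics pipeline
#'
#' Orchestrates the full analysis over a run directory. Stages consume
#' the artifacts of their upstream stage from `outdir` and write their
#' own there, so any suffix of the chain can be rerun; a missing
#' upstream artifact is an error naming it. With identical config and
#' seed the deterministic stages are byte-identical on rerun. Every
#' stage writes a `<stage>_metadata.json` recording the package version,
#' seed, configuration and its MD5.
#'
#' Artifacts: `counts.tsv`, `truth.tsv`, `covariates.tsv` (simulate);
#' `fpkm_raw.tsv`, `fpkm_normalized.tsv`, `binding.tsv` (quantify);
#' `correlations.json`, `stratified_summaries.tsv`, `stratified_ks.tsv`,
#' and optionally `target_shift.json` (associate); `binding_change.tsv`,
#' `stability.tsv`, `dynamics.json` (dynamics).
#'
#' When a `counts` path is configured, quantify starts from that file
#' (with `lengths` required) instead of simulated counts, and associate
#' requires a configured `covariates` table.
#'
#' @param config a `ripbind_config` list from [readRunConfig()] /
#'   [defaultRunConfig()].
#' @param stages subset of c("simulate", "quantify", "associate",
#'   "dynamics"), executed in pipeline order.
#' @param outdir run directory (created if needed); defaults to
#'   `config$outdir`.
#' @return invisibly, a named list of artifact paths written.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        stages = c("simulate", "quantify", "associate", "dynamics"),
                        outdir = config$outdir) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  add <- function(nm, p) written[[nm]] <<- p

  if ("simulate" %in% stages) {
    simCfg <- simulationConfig(
      nGenes = config$n_genes, timePoints = config$time_points,
      proteins = config$proteins, depthTarget = config$depth_target,
      depthSpikein = config$depth_spikein, dispersion = config$dispersion,
      nSpikein = config$n_spikein, nReplicates = config$n_replicates,
      seed = config$seed)
    sim <- simulateRIP(simCfg)
    add("counts", writeCountTable(sim$counts, .artifact(outdir, "counts.tsv")))
    add("truth", writeTruth(sim$truth, .artifact(outdir, "truth.tsv")))
    add("covariates", .writeTSV(.signifCols(truthCovariates(sim$truth)),
                                .artifact(outdir, "covariates.tsv")))
    lenDf <- data.frame(gene_id = truthGenes(sim$truth),
                        length_nt = sim$truth@lengthNt)
    add("lengths", .writeTSV(lenDf[order(lenDf$gene_id), ],
                             .artifact(outdir, "lengths.tsv")))
    add("simulate_metadata",
        .writeJSON(.runMetadata(config, "simulate"),
                   .artifact(outdir, "simulate_metadata.json")))
  }

  if ("quantify" %in% stages) {
    countsPath <- if (!is.null(config$counts)) config$counts
                  else .needArtifact(outdir, "counts.tsv", "quantify")
    lengthsPath <- if (!is.null(config$lengths)) config$lengths
                   else .needArtifact(outdir, "lengths.tsv", "quantify")
    counts <- readCountTable(countsPath, lengths = readGeneLengths(lengthsPath))
    fpkm <- computeFPKM(counts)
    add("fpkm_raw", writeExpressionMatrix(fpkm, .artifact(outdir, "fpkm_raw.tsv")))
    fpkmNorm <- spikeinNormalize(fpkm, counts)
    add("fpkm_normalized",
        writeExpressionMatrix(fpkmNorm, .artifact(outdir, "fpkm_normalized.tsv")))
    expressed <- filterExpressed(fpkm, threshold = config$fpkm_threshold,
                                 mode = config$filter_mode)
    binding <- bindingScore(fpkm, expressed = expressed)
    add("binding", writeBindingTable(binding, .artifact(outdir, "binding.tsv")))
    add("quantify_metadata",
        .writeJSON(c(.runMetadata(config, "quantify"),
                     list(n_expressed = length(expressed),
                          fpkm_threshold = config$fpkm_threshold,
                          filter_mode = config$filter_mode)),
                   .artifact(outdir, "quantify_metadata.json")))
  }

  if ("associate" %in% stages) {
    binding <- readBindingTable(.needArtifact(outdir, "binding.tsv", "associate"))
    covPath <- if (!is.null(config$covariates)) config$covariates
               else .needArtifact(outdir, "covariates.tsv", "associate")
    cov <- readCovariates(covPath)
    res <- associateBindingCovariates(
      binding, cov, residualize = config$residualize,
      nested = config$nested_tertiles)
    add("correlations", .writeJSON(c(res$correlations,
                                     list(metadata = .runMetadata(config, "associate"))),
                                   .artifact(outdir, "correlations.json")))
    add("stratified_summaries",
        .writeTSV(.signifCols(res$stratified@summaries),
                  .artifact(outdir, "stratified_summaries.tsv")))
    add("stratified_ks",
        .writeTSV(.signifCols(res$stratified@ksTests),
                  .artifact(outdir, "stratified_ks.tsv")))
    if (!is.null(config$targets)) {
      targets <- readGeneSet(config$targets)
      delta <- bindingDeltaLastVsFirst(binding, protein = config$proteins[1L])
      shift <- targetSetShift(delta, targets)
      add("target_shift",
          .writeJSON(list(target = as.list(shift$target),
                          background = as.list(shift$background),
                          ks_p = shift$ks$pValue,
                          median_shift = shift$medianShift),
                     .artifact(outdir, "target_shift.json")))
    }
  }

  if ("dynamics" %in% stages) {
    counts <- readCountTable(
      if (!is.null(config$counts)) config$counts
      else .needArtifact(outdir, "counts.tsv", "dynamics"),
      lengths = readGeneLengths(
        if (!is.null(config$lengths)) config$lengths
        else .needArtifact(outdir, "lengths.tsv", "dynamics")))
    binding <- readBindingTable(.needArtifact(outdir, "binding.tsv", "dynamics"))
    fpkm <- computeFPKM(counts)
    fpkmNorm <- spikeinNormalize(fpkm, counts)
    inputLibs <- colnames(fpkmNorm)[colData(fpkmNorm)$fraction == "input"]
    anyExpr <- filterExpressed(fpkmNorm, threshold = config$fpkm_threshold,
                               mode = "any_timepoint", libraries = inputLibs)
    fc <- rnaFoldChange(fpkmNorm, genes = anyExpr)
    add("stability",
        .writeTSV(.signifCols(data.frame(gene_id = rownames(fc), fc,
                                         check.names = FALSE)),
                  .artifact(outdir, "stability.tsv")))
    delta <- bindingChange(binding)
    add("binding_change",
        .writeTSV(.signifCols(data.frame(
          gene_id = rownames(delta),
          assay(delta, "delta_log2_binding"),
          check.names = FALSE)),
          .artifact(outdir, "binding_change.tsv")))
    dyn <- dynamicsSummary(binding, fc, fpkmNorm,
                           protein = config$proteins[1L])
    add("dynamics", .writeJSON(c(dyn, list(metadata = .runMetadata(config, "dynamics"))),
                               .artifact(outdir, "dynamics.json")))
  }

  invisible(written)
}

# Change in binding, last time point vs first, for one protein.
bindingDeltaLastVsFirst <- function(binding, protein) {
  d <- bindingChange(binding)
  cd <- colData(d)
  tps <- levels(cd$time_point)
  col <- which(cd$protein == protein &
                 as.character(cd$time_point) == tps[length(tps)])
  stats::setNames(assay(d, "delta_log2_binding")[, col], rownames(d))
}

#' Binding-covariate association battery
#'
#' The figure-level association analysis in one call: at the first time
#' point, Spearman correlations of the first protein's binding with tail
#' length and TE, tail length with TE, the corrected (partial) binding-TE
#' correlation given tail length, the two proteins' binding correlation
#' at every time point, and the nested quintile-by-tertile
#' stratification of TE by binding and tail length.
#'
#' @param binding a [BindingSet].
#' @param covariates data.frame from [readCovariates()].
#' @param proteins the (decay-coupled, other) protein pair; defaults to
#'   the two proteins present.
#' @param residualize passed to [partialSpearman()].
#' @param nested passed to [stratifiedBins()].
#' @return list with `correlations` (plain list of rho/p/n entries) and
#'   `stratified` (a [StratifiedResult]).
#' @export
associateBindingCovariates <- function(binding, covariates, proteins = NULL,
                                       residualize = "rank", nested = TRUE) {
  cd <- colData(binding)
  if (is.null(proteins)) proteins <- unique(cd$protein)
  tps <- levels(cd$time_point)
  b <- assay(binding, "log2binding")
  cov <- covariates[match(rownames(b), covariates$gene_id), ]
  ok <- !is.na(cov$tail_length) & !is.na(cov$te)

  col1 <- paste0(proteins[1L], "_", tps[1L])
  b1 <- b[ok, col1]
  tail <- cov$tail_length[ok]; te <- cov$te[ok]

  asEntry <- function(cr) list(rho = corRho(cr), p = corP(cr), n = corN(cr))
  corrs <- list(
    binding_vs_tail = asEntry(spearmanCorr(b1, tail)),
    binding_vs_te = asEntry(spearmanCorr(b1, te)),
    tail_vs_te = asEntry(spearmanCorr(tail, te)),
    binding_vs_te_given_tail = asEntry(
      partialSpearman(b1, te, tail, residualize = residualize,
                      covariate = "tail_length")))

  if (length(proteins) >= 2L) {
    cross <- lapply(tps, function(tp) {
      ca <- paste0(proteins[1L], "_", tp); cb <- paste0(proteins[2L], "_", tp)
      if (!all(c(ca, cb) %in% colnames(b))) return(NULL)
      fin <- is.finite(b[, ca]) & is.finite(b[, cb])
      asEntry(spearmanCorr(b[fin, ca], b[fin, cb]))
    })
    names(cross) <- tps
    corrs$protein_cross <- cross[!vapply(cross, is.null, logical(1))]
  }

  strat <- stratifiedBins(primary = b1, secondary = tail, outcome = te,
                          geneIds = rownames(b)[ok], nested = nested)
  list(correlations = corrs, stratified = strat)
}

#' Time-course summary statistics
#'
#' Per-interval Spearman correlation between a protein's binding at the
#' interval start and the RNA fold change over that interval (the
#' repression-to-decay regime readout), the binding correlation matrix
#' across time points, and the cross-time abundance correlation between
#' the first and third time points.
#'
#' @param binding a [BindingSet].
#' @param foldChange matrix from [rnaFoldChange()].
#' @param fpkmNorm normalized [FPKMSet] (for the abundance comparison).
#' @param protein which protein's binding to pair with decay.
#' @param pairing `"start"` (study convention: binding at the interval's
#'   first time point) or `"end"`.
#' @return list of plain summaries, JSON-ready.
#' @export
dynamicsSummary <- function(binding, foldChange, fpkmNorm, protein,
                            pairing = c("start", "end")) {
  pairing <- match.arg(pairing)
  cd <- colData(binding)
  tps <- levels(cd$time_point)
  b <- assay(binding, "log2binding")
  genes <- intersect(rownames(b), rownames(foldChange))

  byInterval <- lapply(seq_len(ncol(foldChange)), function(i) {
    tpIdx <- if (pairing == "start") i else i + 1L
    col <- paste0(protein, "_", tps[tpIdx])
    if (!col %in% colnames(b)) return(NULL)
    fin <- is.finite(b[genes, col]) & is.finite(foldChange[genes, i])
    cr <- spearmanCorr(b[genes, col][fin], foldChange[genes, i][fin])
    list(interval = colnames(foldChange)[i], rho = corRho(cr),
         p = corP(cr), n = corN(cr))
  })
  byInterval <- byInterval[!vapply(byInterval, is.null, logical(1))]

  tcm <- timepointCorrelationMatrix(binding)
  ab <- if (length(tps) >= 3L)
    abundanceComparison(fpkmNorm, tps[1L], tps[3L], genes = genes) else NULL

  out <- list(binding_vs_fold_change = byInterval,
              binding_correlation_matrix = tcm$rho)
  if (!is.null(ab))
    out$abundance_comparison <- list(
      time_a = tps[1L], time_b = tps[3L],
      rho = corRho(ab$correlation), n = corN(ab$correlation))
  out
}
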