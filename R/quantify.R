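#' Compute FPKM from gene-level counts
#'
#' Standard FPKM with one deliberate twist: the per-library denominator
#' counts only target-species reads, so the spike-in amount never leaks
#' into target-gene expression values (and hence into binding).
#' \deqn{FPKM(g, j) = 10^9 \, k_{gj} / (L_g \, N_j)}
#' where \eqn{L_g} is the gene length in nt and \eqn{N_j} the total
#' target-species counts in library j. Spike-in rows receive FPKM on the
#' same denominator; they are dropped by [spikeinNormalize()].
#'
#' @param x a [RIPCountSet].
#' @param ... unused.
#' @return an [FPKMSet] with `metadata(x)$normalized = FALSE`.
#' @examples
#' sim <- simulateRIP(simulationConfig(nGenes = 100, nSpikein = 10, seed = 2))
#' fpkm <- computeFPKM(sim$counts)
#' isNormalized(fpkm)
#' @export
setMethod("computeFPKM", "RIPCountSet", function(x, ...) {
  cnt <- assay(x, "counts")
  len <- rowData(x)$length_nt
  expressed <- rowSums(cnt) > 0
  bad <- expressed & (is.na(len) | len <= 0)
  if (any(bad))
    stop("missing or non-positive length for expressed genes: ",
         paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  tgt <- rowData(x)$species == "target"
  totals <- colSums(cnt[tgt, , drop = FALSE])
  fpkm <- 1e9 * sweep(cnt / len, 2, totals, "/")
  se <- SummarizedExperiment(assays = list(fpkm = fpkm),
                             rowData = rowData(x), colData = colData(x))
  metadata(se)$normalized <- FALSE
  new("FPKMSet", se)
})

#' Apply spike-in scale factors to input libraries
#'
#' The study adds a fixed mass of foreign-species RNA to every input
#' sample, so the number of endogenous reads \emph{per spike-in read}
#' tracks the true amount of endogenous mRNA. Input library j is
#' rescaled by
#' \eqn{s_j = (S_{ref} / S_j) \cdot (N_j / N_{ref})},
#' where \eqn{S_j} is the library's spike-in count total, \eqn{N_j} its
#' target count total (the FPKM denominator), and "ref" is the first
#' time point's input library. The \eqn{N_j/N_{ref}} term undoes the
#' per-library depth normalization baked into FPKM, so the product
#' measures abundance per spike-in read; for libraries sequenced to
#' equal target depth it reduces to the intuitive \eqn{S_{ref}/S_j}.
#' This makes input FPKM comparable across time points (global mRNA
#' degradation becomes visible); IP libraries are left untouched, since
#' binding is computed against the unnormalized input. Spike-in rows
#' are removed from the returned matrix.
#'
#' @param x an [FPKMSet] with `normalized = FALSE`.
#' @param counts the [RIPCountSet] the FPKM were computed from (source
#'   of the spike-in totals).
#' @param ... unused.
#' @return an [FPKMSet] with `normalized = TRUE`, target genes only;
#'   the factors used are stored in `metadata(.)$spikeinFactors`.
#' @export
setMethod("spikeinNormalize", signature(x = "FPKMSet", counts = "RIPCountSet"),
  function(x, counts, ...) {
    if (isNormalized(x))
      stop("expression matrix is already spike-in normalized", call. = FALSE)
    stopifnot(identical(colnames(x), colnames(counts)))
    cd <- colData(x)
    inputLibs <- colnames(x)[cd$fraction == "input"]
    if (!length(inputLibs)) stop("no input libraries found", call. = FALSE)
    spikeRows <- rowData(counts)$species == "spikein"
    cnt <- assay(counts, "counts")
    S <- colSums(cnt[spikeRows, inputLibs, drop = FALSE])
    if (any(S == 0))
      stop("zero spike-in counts in input library: ",
           paste(inputLibs[S == 0], collapse = ", "), call. = FALSE)
    N <- colSums(cnt[!spikeRows, inputLibs, drop = FALSE])
    sFac <- (S[[1L]] / S) * (N / N[[1L]])
    f <- assay(x, "fpkm")
    f[, inputLibs] <- sweep(f[, inputLibs, drop = FALSE], 2, sFac, "*")
    keep <- rowData(x)$species == "target"
    se <- SummarizedExperiment(assays = list(fpkm = f[keep, , drop = FALSE]),
                               rowData = rowData(x)[keep, ], colData = cd)
    metadata(se)$normalized <- TRUE
    metadata(se)$spikeinFactors <- sFac
    new("FPKMSet", se)
  })

#' Expression filter on FPKM
#'
#' The study's two inclusion rules: for binding analyses a gene must
#' exceed the cutoff in \emph{every} relevant library
#' (`mode = "all_timepoints"`); for input-abundance analyses, where large
#' developmental changes are expected, exceeding it in a single library
#' suffices (`mode = "any_timepoint"`).
#'
#' @param x an [FPKMSet] or a plain FPKM matrix.
#' @param threshold FPKM cutoff; retained genes must be strictly above it
#'   (default 0.5).
#' @param mode `"all_timepoints"` or `"any_timepoint"`.
#' @param libraries library (column) names the rule is evaluated over;
#'   defaults to all columns.
#' @param ... unused.
#' @return character vector of retained target-gene ids (lexicographic);
#'   warns if empty.
#' @export
setMethod("filterExpressed", "FPKMSet",
  function(x, threshold = 0.5, mode = c("all_timepoints", "any_timepoint"),
           libraries = colnames(x), ...) {
    m <- assay(x, "fpkm")[rowData(x)$species == "target", , drop = FALSE]
    filterExpressed(m, threshold = threshold, mode = mode, libraries = libraries)
  })

#' @rdname filterExpressed
#' @export
setMethod("filterExpressed", "matrix",
  function(x, threshold = 0.5, mode = c("all_timepoints", "any_timepoint"),
           libraries = colnames(x), ...) {
    mode <- match.arg(mode)
    m <- x[, libraries, drop = FALSE]
    ok <- if (mode == "all_timepoints") rowSums(m > threshold) == ncol(m)
          else rowSums(m > threshold) >= 1L
    genes <- sort(rownames(m)[ok])
    if (!length(genes))
      warning("no genes pass the ", threshold,
              " FPKM filter (mode ", mode, ")", call. = FALSE)
    genes
  })

#' Relative binding from paired IP and input libraries
#'
#' The study's binding statistic: per (protein, time point),
#' \deqn{binding(g) = \log_2\!\big(FPKM_{IP}(g) / FPKM_{input}(g)\big)}
#' computed against the \emph{unnormalized} input and median-centered
#' over the retained genes, so the median log2 binding of all
#' transcripts is exactly 0 — the values are relative, not absolute.
#' Genes must pass the all-time-points expression filter (pass them via
#' `expressed`). Retained genes with zero IP counts are given a
#' pseudo-FPKM of half the smallest nonzero FPKM in that library before
#' the log, preserving rank order instead of producing -Inf; a message
#' reports how many. Replicate libraries of the same condition are
#' averaged on the FPKM scale before the ratio.
#'
#' @param x an [FPKMSet] with `normalized = FALSE` containing both the
#'   IP and input libraries.
#' @param expressed gene ids passing [filterExpressed()] in
#'   `"all_timepoints"` mode.
#' @param proteins which IP proteins to score (default: all present).
#' @param ... unused.
#' @return a [BindingSet], genes x (protein, time point).
#' @examples
#' sim <- simulateRIP(simulationConfig(nGenes = 200, nSpikein = 20, seed = 5))
#' fpkm <- computeFPKM(sim$counts)
#' keep <- filterExpressed(fpkm)
#' b <- bindingScore(fpkm, expressed = keep)
#' summary(assay(b, "log2binding")[, 1])
#' @export
setMethod("bindingScore", "FPKMSet",
  function(x, expressed, proteins = NULL, ...) {
    if (isNormalized(x))
      stop("binding divides by the unnormalized input; got a spike-in normalized matrix",
           call. = FALSE)
    cd <- colData(x)
    if (is.null(proteins))
      proteins <- unique(stats::na.omit(cd$protein))
    if (!length(expressed)) stop("empty expressed gene set", call. = FALSE)
    genes <- sort(intersect(expressed, rownames(x)))
    f <- assay(x, "fpkm")
    tps <- levels(cd$time_point)
    if (is.null(tps)) tps <- unique(as.character(cd$time_point))

    condMean <- function(fraction, protein, tp) {
      sel <- cd$fraction == fraction & as.character(cd$time_point) == tp
      if (fraction == "IP") sel <- sel & cd$protein %in% protein
      if (!any(sel)) return(NULL)
      rowMeans(f[genes, sel, drop = FALSE])
    }

    cols <- list(); protv <- character(); tpv <- character()
    nPseudo <- 0L
    for (p in proteins) for (tp in tps) {
      ip <- condMean("IP", p, tp)
      inp <- condMean("input", NULL, tp)
      if (is.null(ip) || is.null(inp)) next
      zero <- ip == 0
      if (any(zero)) {
        ip[zero] <- min(ip[!zero]) / 2
        nPseudo <- nPseudo + sum(zero)
      }
      drop <- inp == 0
      l2 <- log2(ip / inp)
      l2[drop] <- NA_real_
      if (any(drop))
        warning(sum(drop), " gene(s) with zero input FPKM dropped at ",
                p, " ", tp, call. = FALSE)
      l2 <- l2 - stats::median(l2, na.rm = TRUE)
      nm <- paste0(p, "_", tp)
      cols[[nm]] <- l2; protv <- c(protv, p); tpv <- c(tpv, tp)
    }
    if (!length(cols)) stop("no (protein, time point) pairs with both IP and input libraries",
                            call. = FALSE)
    if (nPseudo > 0L)
      message(nPseudo, " zero IP FPKM value(s) replaced by half-minimum pseudo-FPKM")
    b <- do.call(cbind, cols)
    rownames(b) <- genes
    se <- SummarizedExperiment(
      assays = list(log2binding = b),
      colData = DataFrame(protein = protv,
                          time_point = factor(tpv, levels = tps),
                          row.names = colnames(b)))
    new("BindingSet", se)
  })

#' Enrichment of one protein's binding over another's
#'
#' Per gene and time point, the log2 ratio of the numerator protein's
#' binding to the denominator's (PABP over ME31B in the study, used to
#' probe the PABP complexes that lack ME31B):
#' \eqn{value(g) = log2binding_{num}(g) - log2binding_{den}(g)}.
#'
#' @param x a [BindingSet] containing both proteins.
#' @param numerator,denominator protein labels.
#' @param ... unused.
#' @return matrix, genes x shared time points.
#' @export
setMethod("relativeEnrichment", "BindingSet",
  function(x, numerator = "PABP", denominator = "ME31B", ...) {
    cd <- colData(x)
    tpsN <- as.character(cd$time_point[cd$protein == numerator])
    tpsD <- as.character(cd$time_point[cd$protein == denominator])
    tps <- intersect(tpsN, tpsD)
    if (!length(tps) || !nrow(x))
      stop("no shared (gene, time point) support between ", numerator,
           " and ", denominator, call. = FALSE)
    b <- assay(x, "log2binding")
    out <- sapply(tps, function(tp) {
      b[, cd$protein == numerator & as.character(cd$time_point) == tp] -
        b[, cd$protein == denominator & as.character(cd$time_point) == tp]
    })
    out <- matrix(out, nrow = nrow(b), dimnames = list(rownames(b), tps))
    out
  })

#' Fold enrichment and background fraction from RT-qPCR percentages
#'
#' The IP validation arithmetic: given the percent of a benchmark
#' transcript recovered in the specific IP and in the control IP, the
#' fold enrichment is their ratio and the fraction of the IP signal
#' attributable to background binding is its reciprocal. The study's
#' printed folds of 1,189 (PABP) and 42,000 (ME31B) thus bound the
#' background below 0.1%.
#'
#' @param percentTarget percent input recovered in the specific IP (> 0).
#' @param percentControl percent input recovered in the control IP (> 0).
#' @return list with numeric vectors `fold` and `backgroundFraction`
#'   (a proportion; multiply by 100 for percent).
#' @examples
#' qpcrEnrichment(11.89, 0.01)$fold     # 1189-fold
#' @export
qpcrEnrichment <- function(percentTarget, percentControl) {
  .stopifnotFinite(percentTarget, "percentTarget")
  .stopifnotFinite(percentControl, "percentControl")
  if (any(percentControl <= 0))
    stop("control percentage must be > 0: fold enrichment is undefined", call. = FALSE)
  if (any(percentTarget <= 0))
    stop("target percentage must be > 0", call. = FALSE)
  fold <- percentTarget / percentControl
  list(fold = fold, backgroundFraction = 1 / fold)
}
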