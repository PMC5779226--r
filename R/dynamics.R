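#' Change in binding relative to a reference time point
#'
#' Per gene and protein, \eqn{\Delta(g, t) = log2binding(g, t) -
#' log2binding(g, ref)} — the study's "fold change in binding compared
#' to 0-1 hr". Deltas at the reference time are exactly 0.
#'
#' @param x a [BindingSet].
#' @param referenceTime time-point label of the reference (default: the
#'   first level).
#' @param ... unused.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `delta_log2_binding` and the same column annotation as `x`.
#' @export
setMethod("bindingChange", "BindingSet", function(x, referenceTime = NULL, ...) {
  cd <- colData(x)
  tps <- levels(cd$time_point)
  if (is.null(referenceTime)) referenceTime <- tps[1L]
  if (!referenceTime %in% as.character(cd$time_point))
    stop("reference time point not present: ", referenceTime, call. = FALSE)
  b <- assay(x, "log2binding")
  d <- b
  for (p in unique(cd$protein)) {
    refCol <- which(cd$protein == p & as.character(cd$time_point) == referenceTime)
    if (!length(refCol))
      stop("reference time point missing for protein ", p, call. = FALSE)
    cols <- which(cd$protein == p)
    d[, cols] <- b[, cols, drop = FALSE] - b[, refCol]
  }
  SummarizedExperiment(assays = list(delta_log2_binding = d), colData = cd)
})

#' Per-interval RNA fold change from spike-in normalized inputs
#'
#' For each adjacent pair of time points,
#' \eqn{\Delta(g) = \log_2 FPKM_{norm}(g, t+1) - \log_2 FPKM_{norm}(g, t)}
#' on the spike-in normalized input libraries — the "RNA fold change
#' over the next hour". Without spike-in scaling this quantity is
#' meaningless (per-library FPKM hides global degradation), so an
#' unnormalized matrix is refused. Zeros are floored at half the
#' smallest nonzero normalized FPKM across all input libraries; because
#' the same adjusted values enter every interval, interval fold changes
#' telescope exactly to the total first-to-last change. Replicates are
#' averaged per time point.
#'
#' @param x an [FPKMSet] with `normalized = TRUE`.
#' @param genes optional gene ids to restrict to (typically the
#'   any-time-point input filter).
#' @param ... unused.
#' @return matrix, genes x intervals (named "t1->t2").
#' @export
setMethod("rnaFoldChange", "FPKMSet", function(x, genes = NULL, ...) {
  if (!isNormalized(x))
    stop("rnaFoldChange requires spike-in normalized input FPKM ",
         "(metadata 'normalized' flag is FALSE)", call. = FALSE)
  cd <- colData(x)
  tps <- levels(cd$time_point)
  if (length(tps) < 2L) stop("need at least two time points", call. = FALSE)
  f <- assay(x, "fpkm")
  A <- sapply(tps, function(tp) {
    sel <- cd$fraction == "input" & as.character(cd$time_point) == tp
    rowMeans(f[, sel, drop = FALSE])
  })
  if (!is.null(genes)) A <- A[intersect(rownames(A), genes), , drop = FALSE]
  nz <- A[A > 0]
  if (!length(nz)) stop("all-zero input matrix", call. = FALSE)
  A[A == 0] <- min(nz) / 2
  out <- log2(A[, -1L, drop = FALSE]) - log2(A[, -ncol(A), drop = FALSE])
  colnames(out) <- paste0(tps[-length(tps)], "->", tps[-1L])
  out
})

#' Pairwise Spearman correlations across binding columns
#'
#' All pairwise rank correlations among selected (protein, time point)
#' binding columns on their common finite gene set — the scatter-matrix
#' view of how binding rearranges across the time course and how the
#' PABP-ME31B co-binding correlation decays.
#'
#' @param x a [BindingSet].
#' @param columns column names to include (default: all).
#' @param ... unused.
#' @return list of matrices `rho`, `pValue` and `n`; the diagonal of
#'   `rho` is 1.
#' @export
setMethod("timepointCorrelationMatrix", "BindingSet",
  function(x, columns = colnames(x), ...) {
    b <- assay(x, "log2binding")[, columns, drop = FALSE]
    k <- ncol(b)
    if (k < 2L) stop("need at least two binding columns", call. = FALSE)
    rho <- diag(1, k); p <- diag(0, k); n <- matrix(nrow(b), k, k)
    dimnames(rho) <- dimnames(p) <- dimnames(n) <- list(columns, columns)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ok <- is.finite(b[, i]) & is.finite(b[, j])
      if (sum(ok) < 3L)
        stop("fewer than 3 shared genes between ", columns[i], " and ",
             columns[j], call. = FALSE)
      cr <- spearmanCorr(b[ok, i], b[ok, j])
      rho[i, j] <- rho[j, i] <- corRho(cr)
      p[i, j] <- p[j, i] <- corP(cr)
      n[i, j] <- n[j, i] <- corN(cr)
    }
    diag(p) <- NA_real_
    list(rho = rho, pValue = p, n = n)
  })

#' Cross-time abundance comparison
#'
#' Paired spike-in normalized input abundances at two time points with
#' their Spearman correlation — the scatter used to contrast
#' decay-active and decay-inactive regimes (near the identity, rho close
#' to 1, when nothing decays).
#'
#' @param x an [FPKMSet] with `normalized = TRUE`.
#' @param timeA,timeB time-point labels.
#' @param genes optional gene restriction.
#' @param ... unused.
#' @return list with `data` (data.frame gene_id, fpkm_a, fpkm_b) and
#'   `correlation` (a [CorrelationResult]).
#' @export
setMethod("abundanceComparison", "FPKMSet",
  function(x, timeA, timeB, genes = NULL, ...) {
    if (!isNormalized(x))
      stop("abundanceComparison requires spike-in normalized input FPKM",
           call. = FALSE)
    cd <- colData(x)
    f <- assay(x, "fpkm")
    pick <- function(tp) {
      sel <- cd$fraction == "input" & as.character(cd$time_point) == tp
      if (!any(sel)) stop("time point not present: ", tp, call. = FALSE)
      rowMeans(f[, sel, drop = FALSE])
    }
    a <- pick(timeA); b <- pick(timeB)
    if (!is.null(genes)) {
      keep <- rownames(f) %in% genes
      a <- a[keep]; b <- b[keep]
    }
    df <- data.frame(gene_id = names(a), fpkm_a = unname(a), fpkm_b = unname(b))
    list(data = df, correlation = spearmanCorr(a, b))
  })
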