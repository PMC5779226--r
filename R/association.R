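.newCorrelation <- function(rho, p, n, method, covariate = NA_character_) {
  fl <- .floorP(p)
  new("CorrelationResult", rho = rho, pValue = fl$p, pFloored = fl$floored,
      n = as.integer(n), method = method, covariate = covariate)
}

# t-approximation for the significance of a (partial) rank correlation.
.rankCorP <- function(rho, df) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Spearman rank correlation with the study's reporting conventions
#'
#' Average ranks for ties, rho as the Pearson correlation of the rank
#' vectors, and a two-sided p-value from the t-approximation with n - 2
#' degrees of freedom, floored at 1e-15 (printed as "p < 1e-15").
#' Invariant under strictly monotone transforms of either argument.
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return a [CorrelationResult].
#' @examples
#' spearmanCorr(1:10, log(1:10))   # rho = 1
#' @export
spearmanCorr <- function(x, y) {
  .stopifnotFinite(x, "x"); .stopifnotFinite(y, "y")
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  .newCorrelation(rho, .rankCorP(rho, n - 2L), n, "spearman")
}

#' Covariate-corrected rank correlation ("corrected r_s")
#'
#' The partial Spearman correlation between x and y given z: all three
#' vectors are rank-transformed (average ranks), the ranks of x and of y
#' are residualized on the ranks of z by least squares with intercept,
#' and rho is the Pearson correlation of the residuals; two-sided p from
#' the t-approximation with n - 3 degrees of freedom, floored at 1e-15.
#' This is the construction behind the study's "corrected r_s" values,
#' e.g. the ME31B-binding-vs-TE correlation after correcting for
#' poly(A)-tail length. `residualize = "raw"` residualizes the raw
#' values instead of ranks (sensitivity option).
#'
#' A constant z cannot be corrected for: the function falls back to the
#' plain Spearman correlation with a message. A y identical to z is
#' degenerate and an error.
#'
#' @param x,y,z triple-paired finite numeric vectors, n >= 4.
#' @param residualize `"rank"` (default) or `"raw"`.
#' @param covariate label stored in the result (defaults to the z
#'   expression).
#' @return a [CorrelationResult] with method `"partial_spearman"`.
#' @export
partialSpearman <- function(x, y, z, residualize = c("rank", "raw"),
                            covariate = deparse1(substitute(z))) {
  residualize <- match.arg(residualize)
  .stopifnotFinite(x, "x"); .stopifnotFinite(y, "y"); .stopifnotFinite(z, "z")
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must be triple-paired", call. = FALSE)
  if (n < 4L) stop("need at least 4 triples", call. = FALSE)
  if (identical(y, z))
    stop("y is identical to z: the correction is degenerate", call. = FALSE)
  if (stats::sd(z) == 0) {
    message("covariate is constant; falling back to plain Spearman correlation")
    return(spearmanCorr(x, y))
  }
  if (residualize == "rank") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  rx <- stats::residuals(stats::lm.fit(cbind(1, z), x))
  ry <- stats::residuals(stats::lm.fit(cbind(1, z), y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("residuals are constant after correction; rho undefined", call. = FALSE)
  rho <- stats::cor(rx, ry)
  .newCorrelation(rho, .rankCorP(rho, n - 3L), n, "partial_spearman", covariate)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the
#' two-sided p-value is the asymptotic Kolmogorov approximation (the
#' study reports raw two-tailed K-S p-values throughout). Symmetric in
#' its arguments.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list with `statistic` (D), `pValue`, and sample sizes `n1`, `n2`.
#' @export
ksTwoSample <- function(a, b) {
  .stopifnotFinite(a, "a"); .stopifnotFinite(b, "b")
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), pValue = unname(ht$p.value),
       n1 = length(a), n2 = length(b))
}

# Deterministic near-equal quantile bin assignment: order by value with
# stable lexicographic id tie-break; sizes differ by at most 1 and any
# remainder goes to the lower bins.
.binAssign <- function(values, ids, k) {
  n <- length(values)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  bin <- integer(n)
  bin[order(values, ids)] <- rep(seq_len(k), times = sizes)
  bin
}

.boxStats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  inlier <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    whiskerLow = min(inlier), whiskerHigh = max(inlier))
}

#' Nested quantile stratification with adjacent-bin K-S tests
#'
#' Reproduces the study's quintile-by-tertile analysis: genes are ranked
#' by the primary variable (ME31B binding) into `nPrimary` near-equal
#' bins, then within each primary bin ranked by the secondary variable
#' (mean poly(A)-tail length) into `nSecondary` bins, and the outcome
#' (translational efficiency) is summarized per cell as box-plot
#' statistics (median; box = quartiles; whiskers = range excluding
#' points beyond 1.5 IQR). Corresponding cells of adjacent primary bins
#' are compared by the two-tailed K-S test. Bin sizes within a level
#' differ by at most one; remainders fill the lower bins and ties are
#' broken by gene id, so the assignment is invariant to row permutations.
#'
#' @param primary,secondary,outcome paired numeric vectors over a common
#'   gene set (n >= 30).
#' @param geneIds gene identifiers (default: names of `primary`).
#' @param nPrimary,nSecondary bin counts (defaults 5 and 3).
#' @param nested compute secondary bins within each primary bin (the
#'   study's ordering, default) or globally.
#' @return a [StratifiedResult].
#' @export
stratifiedBins <- function(primary, secondary, outcome,
                           geneIds = names(primary),
                           nPrimary = 5L, nSecondary = 3L, nested = TRUE) {
  .stopifnotFinite(primary, "primary"); .stopifnotFinite(secondary, "secondary")
  .stopifnotFinite(outcome, "outcome")
  n <- length(primary)
  if (length(secondary) != n || length(outcome) != n)
    stop("primary, secondary and outcome must be paired", call. = FALSE)
  if (is.null(geneIds)) geneIds <- sprintf("gene%06d", seq_len(n))
  if (n < 30L) stop("need at least 30 genes to stratify", call. = FALSE)

  pbin <- .binAssign(primary, geneIds, nPrimary)
  sbin <- integer(n)
  if (nested) {
    for (q in seq_len(nPrimary)) {
      idx <- which(pbin == q)
      sbin[idx] <- .binAssign(secondary[idx], geneIds[idx], nSecondary)
    }
  } else {
    sbin <- .binAssign(secondary, geneIds, nSecondary)
  }

  cells <- expand.grid(primaryBin = seq_len(nPrimary),
                       secondaryBin = seq_len(nSecondary))
  sizes <- mapply(function(p, s) sum(pbin == p & sbin == s),
                  cells$primaryBin, cells$secondaryBin)
  if (any(sizes < 2L)) {
    bad <- cells[sizes < 2L, , drop = FALSE][1L, ]
    stop(sprintf("bin (primary %d, secondary %d) has fewer than 2 genes",
                 bad$primaryBin, bad$secondaryBin), call. = FALSE)
  }

  summaries <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- pbin == cells$primaryBin[i] & sbin == cells$secondaryBin[i]
    data.frame(primaryBin = cells$primaryBin[i],
               secondaryBin = cells$secondaryBin[i],
               t(.boxStats(outcome[sel])))
  }))

  ks <- do.call(rbind, lapply(seq_len(nSecondary), function(s) {
    do.call(rbind, lapply(seq_len(nPrimary - 1L), function(q) {
      a <- outcome[pbin == q & sbin == s]
      b <- outcome[pbin == q + 1L & sbin == s]
      kt <- ksTwoSample(a, b)
      data.frame(secondaryBin = s, primaryA = q, primaryB = q + 1L,
                 statistic = kt$statistic, pValue = kt$pValue)
    }))
  }))

  new("StratifiedResult",
      assignment = data.frame(gene_id = geneIds, primaryBin = pbin,
                              secondaryBin = sbin),
      summaries = summaries, ksTests = ks, nested = nested,
      nPrimary = as.integer(nPrimary), nSecondary = as.integer(nSecondary))
}

#' Distribution shift of a gene set against its complement
#'
#' Splits a per-gene statistic (e.g. the change in ME31B binding
#' relative to 0-1 hr) into a target set (SMG- or BRAT-bound genes) and
#' its complement, summarizes both distributions as box statistics, and
#' tests the shift with the two-tailed K-S test.
#'
#' @param delta named numeric vector of per-gene values.
#' @param targets character vector of target gene ids; must intersect
#'   the names of `delta` and leave a non-empty complement.
#' @return list with `target` and `background` box summaries (including
#'   group sizes), `ks` (the [ksTwoSample()] result), and
#'   `medianShift` (target median minus background median).
#' @export
targetSetShift <- function(delta, targets) {
  if (is.null(names(delta))) stop("delta must be named by gene id", call. = FALSE)
  inSet <- names(delta) %in% targets
  if (!any(inSet)) stop("no target genes present in delta", call. = FALSE)
  if (all(inSet)) stop("complement of the target set is empty", call. = FALSE)
  a <- delta[inSet]; b <- delta[!inSet]
  ks <- ksTwoSample(a, b)
  list(target = .boxStats(a), background = .boxStats(b), ks = ks,
       medianShift = unname(stats::median(a) - stats::median(b)))
}
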