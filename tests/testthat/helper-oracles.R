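# Independent brute-force oracles, deliberately naive: they re-derive
# ranks and ECDFs from first principles and never call the package (or
# cor/ks.test) themselves.

# Average ranks by direct counting.
bruteRanks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho as the explicit Pearson formula over brute-force ranks.
bruteSpearman <- function(x, y) {
  rx <- bruteRanks(x); ry <- bruteRanks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Two-sample K-S statistic by evaluating both ECDFs at every pooled point.
bruteKS <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Exhaustive near-equal quantile bin assignment: sort by (value, id),
# walk the bins filling floor(n/k) each plus one extra for the first
# n %% k bins.
bruteBins <- function(values, ids, k) {
  n <- length(values)
  ord <- order(values, ids)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(k), times = sizes)
  bin
}
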