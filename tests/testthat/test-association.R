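test_that("spearmanCorr matches the brute-force rank oracle, ties included", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    # small integer supports force plenty of ties
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(corRho(spearmanCorr(x, y)), bruteSpearman(x, y),
                 tolerance = 1e-12)
  }
  # the documented 7-point, one-tie case against the oracle
  x <- c(3, 1, 4, 1, 5, 9, 2); y <- c(2, 7, 1, 8, 2, 8, 1)
  expect_equal(corRho(spearmanCorr(x, y)), bruteSpearman(x, y))
})

test_that("spearmanCorr is monotone-invariant and handles edge cases", {
  set.seed(3)
  x <- rexp(50)
  expect_equal(corRho(spearmanCorr(x, exp(x))), 1)
  expect_equal(corRho(spearmanCorr(x, -x^3)), -1)
  expect_equal(corRho(spearmanCorr(x, log(x))),
               corRho(spearmanCorr(sqrt(x), x^5)))
  expect_error(spearmanCorr(1:5, rep(2, 5)), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "at least 3")
  # p-value floor and reporting
  set.seed(1)
  z <- rnorm(5000)
  big <- spearmanCorr(z, z + rnorm(5000, sd = 0.1))
  expect_equal(corP(big), 1e-15)
  expect_true(big@pFloored)
})

test_that("partial Spearman removes a mediating covariate and only that", {
  set.seed(11)
  n <- 5000
  # independence: partial ~ plain ~ 0
  x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
  expect_lt(abs(corRho(partialSpearman(x, y, z))), 0.05)
  expect_lt(abs(corRho(spearmanCorr(x, y))), 0.05)

  # x and y associated only through z: partial vanishes, plain does not
  z2 <- rnorm(n)
  x2 <- z2 + rnorm(n); y2 <- z2 + rnorm(n)
  expect_gt(corRho(spearmanCorr(x2, y2)), 0.3)
  expect_lt(abs(corRho(partialSpearman(x2, y2, z2))), 0.05)

  # a z that is a monotone transform of an independent uniform changes nothing
  u <- runif(n)
  expect_equal(corRho(partialSpearman(x2, y2, qnorm(u))),
               corRho(spearmanCorr(x2, y2)), tolerance = 0.02)

  expect_error(partialSpearman(x, y2, y2), "identical to z")
  expect_message(r <- partialSpearman(x2, y2, rep(1, n)), "constant")
  expect_equal(corRho(r), corRho(spearmanCorr(x2, y2)))
})

test_that("partial Spearman recovers a planted partial correlation", {
  # copula shaped on the study's triangle: binding-TE -0.29, binding-tail
  # -0.38, tail-TE 0.38; the implied corrected binding-TE value is ~ -0.19
  S <- defaultLatentCorrelations()
  P <- spearmanToPearson(S)
  idx <- c(1, 4, 3)  # (binding, te, tail)
  planted <- (P[1, 4] - P[1, 3] * P[3, 4]) /
    sqrt((1 - P[1, 3]^2) * (1 - P[3, 4]^2))
  set.seed(12)
  Z <- matrix(rnorm(5000 * 4), ncol = 4) %*% chol(P)
  r <- partialSpearman(Z[, idx[1]], Z[, idx[2]], Z[, idx[3]])
  expect_equal(corRho(r), planted, tolerance = 0.05 / abs(planted))
  expect_equal(corRho(r), -0.19, tolerance = 0.05 / 0.19)
})

test_that("K-S statistic matches the brute-force ECDF oracle", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ksTwoSample(1:4, 5:9)$statistic, 1)
  set.seed(5)
  for (i in 1:40) {
    a <- sample(1:6, sample(2:8, 1), replace = TRUE)
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    kt <- ksTwoSample(a, b)
    expect_equal(kt$statistic, bruteKS(a, b), tolerance = 1e-12)
    expect_equal(kt$statistic, ksTwoSample(b, a)$statistic)
  }
  expect_error(ksTwoSample(1, 1:5), "at least 2")
})

test_that("stratified bin assignment matches exhaustive assignment", {
  set.seed(31)
  n <- 103  # awkward size: remainders in both levels
  ids <- sprintf("g%03d", sample(n))
  primary <- sample(1:20, n, replace = TRUE)  # with ties
  secondary <- rnorm(n)
  outcome <- rnorm(n)
  sr <- stratifiedBins(primary, secondary, outcome, geneIds = ids)
  expect_identical(sr@assignment$primaryBin, bruteBins(primary, ids, 5L))
  for (q in 1:5) {
    idx <- which(sr@assignment$primaryBin == q)
    expect_identical(sr@assignment$secondaryBin[idx],
                     bruteBins(secondary[idx], ids[idx], 3L))
  }
  # near-equal sizes: within a level, differ by at most 1
  expect_lte(diff(range(table(sr@assignment$primaryBin))), 1)
  # permuting the input rows does not change any gene's bin
  perm <- sample(n)
  sr2 <- stratifiedBins(primary[perm], secondary[perm], outcome[perm],
                        geneIds = ids[perm])
  m <- match(sr@assignment$gene_id, sr2@assignment$gene_id)
  expect_identical(sr@assignment$primaryBin, sr2@assignment$primaryBin[m])
  expect_identical(sr@assignment$secondaryBin, sr2@assignment$secondaryBin[m])
})

test_that("stratified summaries and K-S tests behave on constructed outcomes", {
  set.seed(33)
  n <- 600
  ids <- sprintf("g%03d", seq_len(n))
  primary <- rnorm(n); secondary <- rnorm(n)

  # constant outcome: equal medians, K-S p ~ 1
  sr <- stratifiedBins(primary, secondary, rep(1, n), geneIds = ids)
  expect_true(all(sr@summaries$median == 1))
  expect_true(all(sr@ksTests$pValue > 0.999))

  # outcome = -primary: medians strictly decrease across quintiles
  sr2 <- stratifiedBins(primary, secondary, -primary, geneIds = ids)
  for (s in 1:3) {
    med <- sr2@summaries$median[sr2@summaries$secondaryBin == s]
    med <- med[order(sr2@summaries$primaryBin[sr2@summaries$secondaryBin == s])]
    expect_true(all(diff(med) < 0))
  }
  expect_equal(nrow(sr2@ksTests), 4 * 3)
  expect_error(stratifiedBins(primary[1:20], secondary[1:20], primary[1:20],
                              geneIds = ids[1:20]), "at least 30")
})

test_that("additive binding and tail effects on TE show up in every tertile", {
  set.seed(35)
  n <- 5000
  ids <- sprintf("g%04d", seq_len(n))
  binding <- rnorm(n); tail <- rnorm(n)
  te <- -0.8 * binding + 0.8 * tail + rnorm(n, sd = 0.5)
  sr <- stratifiedBins(binding, tail, te, geneIds = ids)
  for (s in 1:3) {
    sel <- sr@summaries$secondaryBin == s
    med <- sr@summaries$median[sel][order(sr@summaries$primaryBin[sel])]
    expect_true(all(diff(med) < 0))
  }
  expect_true(all(sr@ksTests$pValue < 0.01))
})

test_that("target-set shift detects planted gains and rejects degenerate splits", {
  set.seed(37)
  n <- 5000
  delta <- rnorm(n)
  names(delta) <- sprintf("g%04d", seq_len(n))
  targets <- sample(names(delta), n / 10)
  delta[targets] <- delta[targets] + 1
  shift <- targetSetShift(delta, targets)
  expect_lt(shift$ks$pValue, 1e-6)
  expect_equal(shift$medianShift, 1, tolerance = 0.15)
  expect_equal(unname(shift$target["n"]), 500)

  expect_error(targetSetShift(delta, character(0)), "no target genes")
  expect_error(targetSetShift(delta, names(delta)), "complement")
  expect_error(targetSetShift(delta, names(delta)[-1]), "at least 2")
  expect_error(targetSetShift(unname(delta), targets), "named")
})
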