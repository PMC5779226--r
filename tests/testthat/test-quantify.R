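test_that("FPKM matches its definition and is depth-scale invariant", {
  cnt <- matrix(c(5L, 10L, 20L), ncol = 1,
                dimnames = list(c("a", "b", "c"), "input_0-1h"))
  x <- toyCountSet(cnt, lengths = c(500, 1000, 2000))
  f <- fpkmMatrix(computeFPKM(x))
  # hand-evaluated 1e9 * k / (L * N), N = 35
  expect_equal(unname(f[, 1]),
               c(1e9 * 5 / (500 * 35), 1e9 * 10 / (1000 * 35),
                 1e9 * 20 / (2000 * 35)))

  # definition check at round numbers: 10 counts, 1 kb, 1e6 total -> FPKM 10
  cnt2 <- matrix(c(10L, 999990L), ncol = 1,
                 dimnames = list(c("g", "rest"), "input_0-1h"))
  f2 <- fpkmMatrix(computeFPKM(toyCountSet(cnt2, lengths = c(1000, 5000))))
  expect_equal(unname(f2["g", 1]), 10)

  # scaling every count x2 changes nothing
  f3 <- fpkmMatrix(computeFPKM(toyCountSet(cnt * 2L, lengths = c(500, 1000, 2000))))
  expect_equal(f3, f)
})

test_that("FPKM denominator excludes spike-in reads and lengths are mandatory", {
  cnt <- matrix(c(10L, 90L), ncol = 1,
                dimnames = list(c("g", "spike1"), "input_0-1h"))
  x <- toyCountSet(cnt, species = c("target", "spikein"), lengths = c(1000, 1000))
  f <- fpkmMatrix(computeFPKM(x))
  expect_equal(unname(f["g", 1]), 1e9 * 10 / (1000 * 10))  # N = 10, not 100

  y <- toyCountSet(cnt, species = c("target", "spikein"), lengths = c(NA, 1000))
  expect_error(computeFPKM(y), "length for expressed genes: g")
})

test_that("spike-in scale factors follow the per-spike-read definition", {
  # equal spike totals and equal target depth: factors 1, matrix unchanged
  cnt <- cbind("input_0-1h" = c(60L, 40L, 50L),
               "input_1-2h" = c(40L, 60L, 50L))
  rownames(cnt) <- c("g1", "g2", "spike1")
  x <- toyCountSet(cnt, species = c("target", "target", "spikein"))
  f <- computeFPKM(x)
  fn <- spikeinNormalize(f, x)
  expect_true(isNormalized(fn))
  expect_equal(unname(S4Vectors::metadata(fn)$spikeinFactors), c(1, 1))
  expect_equal(fpkmMatrix(fn), fpkmMatrix(f)[1:2, ])
  expect_false("spike1" %in% rownames(fn))

  # doubled spike-in total at equal target depth: factor 0.5
  cnt2 <- cbind("input_0-1h" = c(60L, 40L, 50L),
                "input_1-2h" = c(60L, 40L, 100L))
  rownames(cnt2) <- rownames(cnt)
  x2 <- toyCountSet(cnt2, species = c("target", "target", "spikein"))
  fn2 <- spikeinNormalize(computeFPKM(x2), x2)
  expect_equal(unname(S4Vectors::metadata(fn2)$spikeinFactors), c(1, 0.5))

  # zero spike-in counts: error naming the library
  cnt3 <- cnt2
  cnt3["spike1", 2] <- 0L
  x3 <- toyCountSet(cnt3, species = c("target", "target", "spikein"))
  expect_error(spikeinNormalize(computeFPKM(x3), x3),
               "zero spike-in counts.*input_1-2h")
})

test_that("global 2-fold degradation against a constant spike is recovered", {
  # masses t1: (2, 2, 1), t2: (1, 1, 1); fixed depth 900 reads
  cnt <- cbind("input_0-1h" = c(360L, 360L, 180L),
               "input_1-2h" = c(300L, 300L, 300L))
  rownames(cnt) <- c("g1", "g2", "spike1")
  x <- toyCountSet(cnt, species = c("target", "target", "spikein"))
  f <- computeFPKM(x)
  raw <- fpkmMatrix(f)
  # unnormalized per-library FPKM can't see the degradation
  expect_equal(raw["g1", 1], raw["g1", 2])
  fn <- fpkmMatrix(spikeinNormalize(f, x))
  expect_equal(unname(fn["g1", 2] / fn["g1", 1]), 0.5)
  expect_equal(unname(fn["g2", 2] / fn["g2", 1]), 0.5)
})

test_that("spike-in normalization preserves within-library gene ratios", {
  sim <- simulateRIP(smallConfig(seed = 17))
  f <- computeFPKM(sim$counts)
  fn <- spikeinNormalize(f, sim$counts)
  g <- intersect(rownames(fn), rownames(f))
  for (lib in colnames(fn)) {
    r0 <- fpkmMatrix(f)[g, lib]
    r1 <- fpkmMatrix(fn)[g, lib]
    nz <- r0 > 0
    expect_equal(stats::sd(r1[nz] / r0[nz]), 0)
  }
})

test_that("expression filters implement the two inclusion rules", {
  m <- rbind(allhigh = c(0.6, 0.6, 0.6, 0.6, 0.6),
             once = c(0.6, 0.1, 0.1, 0.1, 0.1),
             never = c(0.1, 0.2, 0.3, 0.4, 0.5),
             border = c(0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(m) <- paste0("input_", c("0-1h", "1-2h", "2-3h", "3-4h", "4-5h"))
  expect_identical(filterExpressed(m, mode = "all_timepoints"), "allhigh")
  expect_identical(filterExpressed(m, mode = "any_timepoint"),
                   sort(c("allhigh", "once")))
  # strictly-greater rule: 0.5 exactly never qualifies
  expect_false("border" %in% filterExpressed(m, mode = "any_timepoint"))
  # brute force over a random toy table
  set.seed(42)
  m2 <- matrix(runif(50, 0, 1.2), 10,
               dimnames = list(sprintf("g%02d", 1:10), colnames(m)))
  expAll <- sort(rownames(m2)[apply(m2 > 0.5, 1, all)])
  expAny <- sort(rownames(m2)[apply(m2 > 0.5, 1, any)])
  expect_identical(filterExpressed(m2, mode = "all_timepoints"), expAll)
  expect_identical(filterExpressed(m2, mode = "any_timepoint"), expAny)
  expect_warning(filterExpressed(m2, threshold = 10), "no genes pass")
})

test_that("binding is the median-centered log2 IP/input ratio", {
  # ratios 1,2,4,8,16 -> centered -2..2 regardless of library depths
  cnt <- cbind("input_0-1h" = rep(16L, 5),
               "ME31B_0-1h" = c(16L, 32L, 64L, 128L, 256L))
  rownames(cnt) <- paste0("g", 1:5)
  x <- toyCountSet(cnt)
  b <- bindingScore(computeFPKM(x), expressed = rownames(cnt))
  expect_equal(unname(bindingMatrix(b)[, "ME31B_0-1h"]), c(-2, -1, 0, 1, 2))

  # IP == input: all binding exactly 0
  cnt2 <- cbind("input_0-1h" = c(5L, 10L, 20L), "ME31B_0-1h" = c(5L, 10L, 20L))
  rownames(cnt2) <- paste0("g", 1:3)
  b2 <- bindingScore(computeFPKM(toyCountSet(cnt2)), expressed = rownames(cnt2))
  expect_equal(unname(bindingMatrix(b2)[, 1]), rep(0, 3))

  # refuses a spike-in normalized matrix
  sim <- simulateRIP(smallConfig(seed = 19))
  fn <- spikeinNormalize(computeFPKM(sim$counts), sim$counts)
  expect_error(bindingScore(fn, expressed = rownames(fn)), "unnormalized input")
})

test_that("binding is invariant under uniform rescaling of one library", {
  sim <- simulateRIP(smallConfig(seed = 23))
  cnt <- SummarizedExperiment::assay(sim$counts, "counts")
  keep <- filterExpressed(computeFPKM(sim$counts))
  b1 <- bindingMatrix(bindingScore(computeFPKM(sim$counts), expressed = keep))
  cnt2 <- cnt
  cnt2[, "ME31B_1-2h"] <- cnt2[, "ME31B_1-2h"] * 3L
  x2 <- toyCountSet(cnt2,
                    species = SummarizedExperiment::rowData(sim$counts)$species,
                    lengths = SummarizedExperiment::rowData(sim$counts)$length_nt)
  b2 <- bindingMatrix(bindingScore(computeFPKM(x2), expressed = keep))
  expect_equal(b2, b1)
})

test_that("zero-IP genes get the half-minimum pseudo-FPKM with a message", {
  cnt <- cbind("input_0-1h" = rep(100L, 6),
               "ME31B_0-1h" = c(0L, 10L, 20L, 40L, 80L, 160L))
  rownames(cnt) <- paste0("g", 1:6)
  expect_message(
    b <- bindingScore(computeFPKM(toyCountSet(cnt)), expressed = rownames(cnt)),
    "pseudo-FPKM")
  v <- bindingMatrix(b)[, 1]
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["g1"]), unname(v["g2"]) - 1)  # half of min nonzero (10)
  expect_identical(names(sort(v)), paste0("g", 1:6))
})

test_that("relative enrichment is the log2 binding difference on shared genes", {
  cnt <- cbind("input_0-1h" = rep(100L, 5),
               "ME31B_0-1h" = c(25L, 50L, 100L, 200L, 400L),
               "PABP_0-1h" = c(400L, 200L, 100L, 50L, 25L))
  rownames(cnt) <- paste0("g", 1:5)
  b <- bindingScore(computeFPKM(toyCountSet(cnt)), expressed = rownames(cnt))
  e <- relativeEnrichment(b, numerator = "PABP", denominator = "ME31B")
  expect_equal(unname(e[, "0-1h"]), c(4, 2, 0, -2, -4))
  # identical tables -> zeros
  cnt2 <- cnt; cnt2[, "PABP_0-1h"] <- cnt2[, "ME31B_0-1h"]
  b2 <- bindingScore(computeFPKM(toyCountSet(cnt2)), expressed = rownames(cnt2))
  expect_equal(unname(relativeEnrichment(b2)[, 1]), rep(0, 5))
  expect_error(relativeEnrichment(b, numerator = "EIF4G"), "no shared")
})

test_that("qPCR enrichment arithmetic bounds the background fraction", {
  r <- qpcrEnrichment(c(11.89, 42), c(0.01, 0.001))
  expect_equal(r$fold, c(1189, 42000))
  expect_equal(r$backgroundFraction, 1 / c(1189, 42000))
  expect_true(all(r$backgroundFraction < 0.001))  # below 0.1%
  expect_equal(qpcrEnrichment(5, 5)$fold, 1)
  expect_equal(qpcrEnrichment(5, 5)$backgroundFraction, 1)
  expect_error(qpcrEnrichment(5, 0), "control percentage")
})

test_that("pipeline binding tracks planted affinity on simulations", {
  sim <- simulateRIP(smallConfig(seed = 29))
  f <- computeFPKM(sim$counts)
  b <- bindingScore(f, expressed = filterExpressed(f))
  for (p in c("ME31B", "PABP")) {
    est <- bindingMatrix(b)[, paste0(p, "_0-1h")]
    planted <- truthAffinity(sim$truth)[names(est), p]
    expect_gt(corRho(spearmanCorr(est, planted)), 0.9)
  }
})
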