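# ripbind

Quantification and association analysis for RIP-seq time courses, built
around the maternal-to-zygotic transition (MZT) of the early *Drosophila*
embryo. During the MZT, maternal mRNAs that were translationally
repressed by the DEAD-box helicase ME31B (in complexes that also contain
PABP) are handed over to the decay machinery; the analytical question is
how per-gene binding of these proteins relates to poly(A)-tail length,
translational efficiency (TE), and subsequent mRNA decay, hour by hour.

`ripbind` is for analysts working from gene-level count tables of paired
immunoprecipitation (IP) and input libraries across time points, with a
constant foreign-species RNA spike-in in the inputs.

## The statistics at the core

**Relative binding.** For gene *g*, protein *P* and time point *t*,

```
binding_P(g, t) = log2( FPKM_IP(g, t) / FPKM_input(g, t) ) − median over expressed genes
```

computed against the *unnormalized* input, so the median log2 binding of
all retained transcripts is exactly 0: binding is relative, not
absolute. FPKM uses only target-species reads in its per-library
denominator, so the spike-in amount never contaminates binding. Genes
must exceed 0.5 FPKM in every library (binding analyses) or in at least
one (input-abundance analyses).

**Spike-in normalization.** Input library *j* is rescaled by
`s_j = (S_ref/S_j) · (N_j/N_ref)` — spike-in counts `S`, target counts
`N` — which measures abundance per spike-in read and makes global mRNA
degradation visible across time points.

**Associations.** Tie-aware Spearman correlation r_s (t-approximation,
p floored at 1e-15); "corrected r_s", the partial rank correlation
after residualizing both rank vectors on a covariate's ranks; two-sided
two-sample Kolmogorov–Smirnov tests; nested quantile stratification
(binding quintiles, then tail-length tertiles, with adjacent-quintile
K-S tests on TE); and gene-set shift tests for SMG-/BRAT-target genes.

**Dynamics.** Binding change relative to the first time point, per-hour
RNA fold change on spike-in-normalized inputs, binding-vs-decay
correlations per interval, and cross-time abundance scatters.

**Synthetic experiments.** A Gaussian-copula generator plants Spearman
correlations among (ME31B affinity, PABP affinity, tail length, TE),
exact marginals, negative-binomial libraries, a >10-fold decline of IP
capture efficiency across the time course, and a decay regime that is
binding-independent in the first hour and binding-coupled afterwards —
so every statistic above can be validated against known truth.

## Worked example

```r
library(ripbind)

cfg <- simulationConfig(nGenes = 2000, nSpikein = 200, seed = 42)
sim <- simulateRIP(cfg)                         # truth + abundances + counts
fpkm <- computeFPKM(sim$counts)
expressed <- filterExpressed(fpkm)              # > 0.5 FPKM in every library
binding <- bindingScore(fpkm, expressed = expressed)

b <- SummarizedExperiment::assay(binding, "log2binding")
cov <- truthCovariates(sim$truth)
cov <- cov[match(rownames(b), cov$gene_id), ]

spearmanCorr(b[, "ME31B_0-1h"], cov$te)
#> r_s = -0.254, p < 1e-15, n = 1905
partialSpearman(b[, "ME31B_0-1h"], cov$te, cov$tail_length,
                covariate = "tail_length")
#> corrected r_s (given tail_length) = -0.148, p = 9.38e-11, n = 1905
spearmanCorr(b[, "ME31B_0-1h"], b[, "PABP_0-1h"])
#> r_s = 0.629, p < 1e-15, n = 1905
```

High ME31B binding goes with low TE (r_s = −0.254); part of that
relationship is carried by short poly(A) tails, but a direct component
survives the correction (corrected r_s = −0.148); ME31B and PABP bind
largely the same transcripts (r_s = 0.629). The regime switch shows up
in decay:

```r
fn <- spikeinNormalize(fpkm, sim$counts)
fc <- rnaFoldChange(fn)                          # log2 per-hour fold change
g <- intersect(rownames(b), rownames(fc))
spearmanCorr(b[g, "ME31B_0-1h"], fc[g, 1])       # first hour: no coupling
#> r_s = 0.003, p = 0.882, n = 1905
spearmanCorr(b[g, "ME31B_1-2h"], fc[g, 2])       # after the switch
#> r_s = -0.430, p < 1e-15, n = 1905
```

Bound transcripts do not decay faster in the first interval, and do in
the second. The qPCR arithmetic used to validate an IP:

```r
q <- qpcrEnrichment(c(11.89, 4.2), c(0.01, 0.0001))
#> fold = 1189 / 42000; background = 0.084% / 0.0024%
```

A fold enrichment of the benchmark transcript of 1,189 (or 42,000)
bounds the fraction of its IP signal attributable to background binding
below 0.1%.

`runPipeline()` (or the `inst/scripts/ripbind` CLI with subcommands
`simulate`, `quantify`, `associate`, `dynamics`, `all`) runs the whole
chain over a directory of TSV/JSON artifacts; see `?runPipeline` for
the artifact list and `?readRunConfig` for the configuration schema.

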