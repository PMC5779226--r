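---
title: "Quantifying RIP-seq binding across the maternal-to-zygotic transition: models and design choices"
author: "ripbind maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RIP-seq binding across the MZT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripbind)
```

## The measurement model

A RIP-seq time course pairs, at each developmental window, an input
library (total RNA) with one IP library per immunoprecipitated protein.
`ripbind` starts from gene-level counts. Expression is FPKM,

$$\mathrm{FPKM}(g, j) = \frac{10^9\, k_{gj}}{L_g\, N_j},$$

with gene length $L_g$ in nucleotides and $N_j$ the library's total
*target-species* counts. Excluding spike-in reads from $N_j$ is
deliberate: the amount of foreign RNA spiked into a sample is an
experimental constant, and letting it into the denominator would make
binding depend on it.

The central statistic is **relative binding**: per protein and time
point,

$$b(g) = \log_2 \frac{\mathrm{FPKM}_{IP}(g)}{\mathrm{FPKM}_{input}(g)}
        - \operatorname{median}_{g'} \log_2
          \frac{\mathrm{FPKM}_{IP}(g')}{\mathrm{FPKM}_{input}(g')}.$$

Two aspects deserve emphasis. First, the divisor is the
*unnormalized* input: binding compares the IP against the same
sample's RNA pool, so cross-time abundance rescaling must not touch
it. Second, the median anchor: IP efficiency differs between
antibodies and declines as the immunoprecipitated proteins are
degraded across the MZT, so absolute recovery is not identifiable from
sequencing alone. Median-centering makes the values explicitly
relative and reproduces the convention that the median log2 binding of
all transcripts is 0. `bindingScore()` enforces this exactly; the
`BindingSet` validity check tolerates 1e-4 only so that tables
round-tripped through 6-significant-digit TSV remain valid.

**Expression filters.** Binding analyses demand > 0.5 FPKM in *every*
relevant library; input-abundance analyses, where large developmental
changes are expected, demand it in at least one. The threshold is
strict (`>`), and both rules are exposed via `filterExpressed(mode=)`.

**Zero handling.** A retained gene with zero IP counts would give
$-\infty$; it instead receives half the smallest nonzero FPKM in that
library, preserving rank order, with a message. A zero *input* for a
retained gene cannot occur when the filters are applied; if
encountered anyway the gene is dropped from that time point with a
warning rather than imputed, since the input is the denominator of the
statistic itself.

**Spike-in normalization.** Every input sample receives the same mass
of foreign-species RNA before library preparation. Because libraries
are sequenced to an approximately fixed read total, the spike-in's
share of reads grows as the endogenous transcriptome is degraded.
Abundance comparable across time points is abundance *per spike-in
read*: library $j$ is rescaled by

$$s_j = \frac{S_{ref}}{S_j}\cdot\frac{N_j}{N_{ref}},$$

where $S_j$ are spike-in counts and $N_j$ target counts. The second
factor undoes the per-library depth normalization inside FPKM; without
it, a uniform 2-fold degradation against a constant spike would appear
as only ~1.7-fold (the varying $N_j$ fails to cancel), which is easy
to verify on a two-gene example. For libraries with equal target depth
the factor reduces to the familiar $S_{ref}/S_j$.

## Association statistics

`spearmanCorr()` uses average ranks for ties and tests with the
t-approximation on $n-2$ degrees of freedom. The *corrected r_s* of
`partialSpearman()` is the standard rank-based partial correlation:
rank-transform all three vectors, residualize the ranks of $x$ and $y$
on the ranks of $z$ by least squares with intercept, and correlate the
residuals ($n-3$ df). Residualizing raw values instead of ranks is
available (`residualize = "raw"`) and recorded in output metadata, but
rank-based is the default: it is the construction under which calling
the result an $r_s$ is coherent. Two degenerate cases are handled
explicitly: a constant covariate cannot be corrected for (fall back to
plain Spearman, with a message), and $y \equiv z$ makes the correction
meaningless (error). p-values are floored at $10^{-15}$, matching the
reporting convention "p < 10^-15"; the floor is a reporting choice,
not a test modification, and the flag is kept on the result object.

`ksTwoSample()` reports the exact supremum distance between empirical
CDFs with the asymptotic two-sided p-value; raw p-values are reported
throughout, with no multiplicity correction, mirroring how such
stratified panels are annotated.

**Stratification.** `stratifiedBins()` ranks genes into 5 near-equal
primary bins (binding quintiles), then into 3 secondary bins within
each primary bin (tail-length tertiles). Nesting follows the order of
operations in the figure legends this reproduces ("binned into
quintiles ... and then into thirds") and keeps every cell at ~n/15
genes; global tertiles are available via `nested = FALSE` for
sensitivity. Bin assignment is by rank with two deterministic rules:
remainders go to the lower bins, and ties break by lexicographic gene
id — so the assignment is invariant under row permutations of the
input, which the tests check. Box summaries use quartiles with Tukey
whiskers (range excluding points beyond 1.5 IQR); adjacent quintiles
are compared cell-by-cell with K-S tests.

## The synthetic experiment generator

The generator exists so the whole pipeline can be exercised against
known truth. It emulates the study design: five one-hour windows, one
input plus ME31B and PABP IP libraries per window (one replicate by
default, as in the presented data; `nReplicates` exists for variance
studies), a 500-gene spike-in block of constant abundance present only
in inputs, and IP capture efficiency declining >10-fold across the
time course (`captureEfficiency`, default `1 ... 0.08`), emulating the
degradation of the immunoprecipitated proteins themselves.

**Latent structure.** Per-gene (ME31B affinity, PABP affinity, tail
length, TE) are drawn from a Gaussian copula whose correlation matrix
is the exact conversion $\rho_P = 2\sin(\pi \rho_S/6)$ of the target
Spearman matrix, so planted values are directly comparable to pipeline
output. Defaults (`defaultLatentCorrelations()`) encode the 0-1 hr
associations: ME31B–PABP 0.62, ME31B–tail −0.38, ME31B–TE −0.29,
tail–TE 0.38, PABP–tail 0 (the study found essentially none); PABP–TE
is unconstrained by the study and set to −0.18, near the product of
the two paths through ME31B. A non-positive-semi-definite matrix after
conversion is rejected, naming the offending eigenvalue. Marginals:
affinities log-normal (natural-log SD 1 — a ±4 log2-unit binding
spread), tail length log-normal (median 60 nt, sdlog 0.4), TE normal
on log2 (SD 1), initial abundance and gene length log-normal.

**Counts.** Input libraries sequence the combined target + spike pool
at fixed total depth (default 4e7 target + 2e6 spike-in reads at the
reference time point), so the spike share grows as targets decay —
exactly the signal the normalization exploits. IP expected counts are
abundance × length × affinity × capture efficiency, anchored at the
first time point, so halving capture efficiency halves expected yield
without reordering genes. Counts are negative binomial with
`dispersion` (default 0.005) as the reciprocal size; dispersion 0
gives Poisson.

**Decay.** Interval $i$ gives gene $g$ the rate

$$r_i(g) = \mathrm{softplus}\big(\beta_i - c_i z_g + \sigma u_{gi}\big),$$

with $z_g$ the standardized ME31B affinity, $c_i$ the
`decayCoupling`, and $u_{gi}$ a per-gene, per-interval standard-normal
stability effect ($\sigma$ = `decayGeneSD`, default 1.5). Defaults
$c = (0, -1, -1, -1)$ and $\beta = (-1.5, -1, -1, -1)$: in the first
interval decay is binding-independent and slower (maternal transcripts
are comparatively stable before zygotic genome activation); afterwards
highly bound transcripts decay faster — the repression-to-decay regime
switch. Negative coupling meaning "binding promotes decay" is the sign
convention under which the planted pattern (no correlation in interval
one, negative correlation later) comes out of the model; spike-in
genes have zero affinity and zero decay.

Three quantitative choices here were made jointly, and the reasoning
is worth recording. The binding score at time $t$ and the fold change
over $t \to t{+}1$ share the input library at $t$, so per-gene library
noise (variance $\phi_{eff} \approx$ dispersion + $1/\mu$) appears in
both with the same sign and induces a spurious positive correlation of
about $\sqrt{\phi_{eff}/2}$ whenever the interval's true fold-change
variance is negligible. Separately, if the gene-level stability effect
were shared across intervals, the all-time-points expression filter
would preferentially remove jointly high-(affinity, instability) genes
and induce a selection correlation of similar size. Drawing $u_{gi}$
independently per interval removes the selection channel (pre-MZT
basal turnover and MZT-activated decay are driven by different
machinery, so independent heterogeneity is also the biologically
neutral assumption) while giving the first interval enough true
fold-change variance to dilute the shared-noise channel; dispersion
0.005 — the scale of technical library noise for preps from a common
lysate pool — and 4e7-read libraries keep $\phi_{eff}$ small enough
that the binding-independent interval shows |r_s| < 0.05. With
substantially larger dispersion, no setting of the other parameters
keeps that interval clean, because the shared-library term is
irreducible.

**What the generator does not emulate.** No zygotic transcription (all
targets only decay), no isoforms or reads (gene-level counts only), no
per-time-point covariate dynamics (tail length and TE are static gene
properties, while in the embryo both change), no replicate-level
biological variance structure, and no binding heterogeneity along a
transcript. Passing recovery tests therefore demonstrates the
statistics' correctness and the pipeline's calibration — not that real
libraries satisfy the generative assumptions.

## Problem sizes and determinism

Analyses in the test-suite and the acceptance script use the default
design (5000 target + 500 spike-in genes, 15 libraries) for recovery
and regime checks, 10-seed suites for regime recovery, 50-seed suites
for null calibration of the stratified K-S tests, and few-hundred-gene
designs for integration tests — sizes at which Monte-Carlo error on a
Spearman correlation (~1/sqrt(n) ≈ 0.014) is well inside the ±0.05
recovery bands. All randomness flows from a single integer seed per
simulation; truth generation and count drawing use separate derived
streams, and rerunning any stage with the same configuration is
byte-identical.

## Known limitations

* Binding is relative; comparing absolute recovery between proteins or
  across time points requires external anchoring (e.g. a benchmark
  transcript's RT-qPCR enrichment), which the package reports but does
  not use as a normalization.
* The spike-in factor assumes the spiked mass per sample is truly
  constant and that spike-in quantification noise is small; with few
  spike-in genes the factor's sampling noise adds a shared per-interval
  offset to fold changes (it cancels from rank correlations but not
  from absolute fold-change values).
* The partial rank correlation removes the *rank-linear* contribution
  of the covariate only; strongly non-monotone confounding would
  survive the correction.
* K-S p-values are asymptotic; for the ~n/15-gene cells of the
  stratified analysis they are slightly conservative, which the null
  calibration suite quantifies.
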