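Package: ripbind
Title: RIP-Seq Binding Quantification and Association Analysis Across the
    Maternal-to-Zygotic Transition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies relative per-gene binding from paired RNA
    immunoprecipitation (RIP-seq) and input libraries, applies spike-in
    normalization for cross-time-point mRNA abundance comparisons, and
    implements the downstream association statistics used to relate binding
    to poly(A)-tail length, translational efficiency and mRNA decay during
    the Drosophila maternal-to-zygotic transition: tie-aware Spearman
    correlation, covariate-corrected ("corrected r_s") partial rank
    correlation, two-sample Kolmogorov-Smirnov tests, nested quantile
    stratification, and gene-set shift tests. A negative-binomial,
    Gaussian-copula synthetic-data generator emulates the study design
    (paired IP/input libraries for two proteins across five one-hour time
    points, constant foreign-species spike-in, and a translational
    repression to decay regime switch) so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
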