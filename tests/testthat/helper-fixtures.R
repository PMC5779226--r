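# A hand-sized RIPCountSet built from an explicit matrix.
toyCountSet <- function(counts, species = rep("target", nrow(counts)),
                        lengths = rep(1000, nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  RIPCountSet(counts = counts, species = species, lengthNt = lengths)
}

# Small but fully featured simulation for integration-style tests.
smallConfig <- function(seed = 101, ...) {
  simulationConfig(nGenes = 400L, nSpikein = 40L,
                   depthTarget = 4e6, depthSpikein = 2e5,
                   seed = seed, ...)
}

bindingMatrix <- function(b) SummarizedExperiment::assay(b, "log2binding")
fpkmMatrix <- function(f) SummarizedExperiment::assay(f, "fpkm")
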