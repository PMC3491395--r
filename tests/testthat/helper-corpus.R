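# one shared corpus + decoration run per session (built lazily; ~45 s)
.shared <- new.env(parent = emptyenv())

sharedCorpus <- function() {
  if (is.null(.shared$corpus))
    .shared$corpus <- simulateCorpus(simulationConfig(seed = 7))
  .shared$corpus
}

sharedRun <- function() {
  if (is.null(.shared$run))
    .shared$run <- runDecoration(sharedCorpus())
  .shared$run
}

surveyedTruth <- function() {
  tr <- sharedCorpus()$truth
  tr[tr$surveyed, ]
}

gr1 <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}
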