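#!/usr/bin/env Rscript
# Thin CLI over the pipeline entry points.
# Usage:
#   Rscript scripts/decorate.R simulate --out-dir DIR [--seed N]
#   Rscript scripts/decorate.R decorate --out-dir DIR
#   Rscript scripts/decorate.R report   --out-dir DIR

suppressPackageStartupMessages(library(pseudoDecoR))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args) || !args[1] %in% c("simulate", "decorate", "report")) {
  cat("usage: decorate.R {simulate|decorate|report} --out-dir DIR [--seed N]\n")
  quit(status = 1L)
}
cmd <- args[1]
getOpt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
outDir <- getOpt("--out-dir", "decor_run")
seed <- as.integer(getOpt("--seed", "1"))

status <- tryCatch({
  runPipeline(cmd, outDir, seed = seed)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
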