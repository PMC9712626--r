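# Shared settings for the analysis drivers. Each numbered script can be run
# from the repository root as:  Rscript analysis/0X_*.R [--seed N]
suppressMessages(library(irtax))

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
SIMDIR <- "results/simdata"
resdir <- function(stage) {
  d <- file.path("results", stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
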