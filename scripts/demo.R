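#!/usr/bin/env Rscript
# Thin shell wrapper over suigrad::run_demo().
#
#   Rscript scripts/demo.R --seed 1 --out demo_out

suppressMessages(library(suigrad))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  ix <- which(args == flag)
  if (length(ix) && ix < length(args)) args[ix + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out", file.path("demo_out", sprintf("seed%d", seed)))

run_demo(seed = seed, out_dir = out_dir)
cat("outputs in", out_dir, "\n")
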