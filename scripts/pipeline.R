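#!/usr/bin/env Rscript
# Thin command-line wrapper over run_full_pipeline(): generates a complete
# synthetic study and writes every result table plus the run manifest.
#
# Usage: Rscript scripts/pipeline.R --seed <int> --out <dir>

suppressPackageStartupMessages(library(mitophen))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "pipeline_out")

report <- run_full_pipeline(synth_config(), seed = seed, out_dir = out)
print(report)
message("tables written to ", out)
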