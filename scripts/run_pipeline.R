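#!/usr/bin/env Rscript
# Run the full analysis pipeline from a YAML config.
#
# Usage: Rscript scripts/run_pipeline.R --config config.yaml

suppressPackageStartupMessages(library(forumdyn))

args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--config")
if (length(i) != 1L || i == length(args)) {
  stop("usage: Rscript scripts/run_pipeline.R --config config.yaml",
       call. = FALSE)
}
report <- run_pipeline(args[i + 1L])
message("selected k: ", report$clusters$k,
        "; sessions: ", report$sessions$n_sessions,
        "; max-core Sexual fraction: ",
        round(report$network$core_fractions$Sexual, 3))
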