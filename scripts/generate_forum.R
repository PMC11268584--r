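#!/usr/bin/env Rscript
# Generate a synthetic forum event log with ground truth.
#
# Usage: Rscript scripts/generate_forum.R --seed 42 --out events.csv \
#          --categories categories.csv --truth truth.json [--users 500]

suppressPackageStartupMessages(library(forumdyn))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(arg_val("--seed", "42"))
out <- arg_val("--out", "events.csv")
cat_out <- arg_val("--categories", "categories.csv")
truth_out <- arg_val("--truth", "truth.json")
n_users <- as.integer(arg_val("--users", "500"))

cfg <- forum_config(n_users = n_users, seed = seed)
sim <- simulate_forum(cfg, seed = seed)
write_event_log(sim$events, out)
write_categories(sim$categories, cat_out)
jsonlite::write_json(
  list(seed = seed, n_users = n_users,
       total_sessions = sim$truth$total_sessions,
       users = sim$truth$users),
  truth_out, auto_unbox = TRUE, digits = NA)
message(sprintf("wrote %d events for %d users -> %s", nrow(sim$events),
                n_users, out))
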