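#!/usr/bin/env Rscript
# Command-line front end for the pipeline stages.
#
# Usage:
#   Rscript scripts/run_pipeline.R <command> --out <dir> [--config <file>] [--seed <int>]
#
# Commands: simulate | extract | train | evaluate | compare | run-all

suppressPackageStartupMessages(library(cuffless))

usage <- function() {
  cat("usage: Rscript scripts/run_pipeline.R <command> --out <dir>",
      "[--config <file>] [--seed <int>]\n",
      "commands: simulate | extract | train | evaluate | compare | run-all\n")
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) { usage(); quit(status = 2L) }
command <- args[1L]
opt <- list(config = NULL, out = NULL, seed = NULL)
i <- 2L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt) || i == length(args)) { usage(); quit(status = 2L) }
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$out)) { usage(); quit(status = 2L) }

stage <- if (command == "run-all") NULL else command
valid <- c("simulate", "extract", "train", "evaluate", "compare", "run-all")
if (!command %in% valid) {
  message("unknown command '", command, "'"); usage(); quit(status = 2L)
}

status <- tryCatch({
  cfg <- if (is.null(opt$config)) demo_config() else load_config(opt$config)
  run_pipeline(cfg, out_dir = opt$out,
               stages = if (is.null(stage)) c("simulate", "extract", "train",
                                              "evaluate", "compare") else stage,
               seed = if (is.null(opt$seed)) NULL else as.integer(opt$seed))
  message("[", command, "] done; artifacts in ", opt$out)
  0L
}, error = function(e) {
  message("[", command, "] error: ", conditionMessage(e))
  1L
})
quit(status = status)
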