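#!/usr/bin/env Rscript

# Thin command-line wrapper around prscreen::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config <run.yaml> [--out <dir>]
#
# The YAML config is documented in ?validate_config. --out overrides the
# config's output_dir. Exit codes: 0 success, 2 configuration error,
# 1 any other failure.

suppressPackageStartupMessages(library(prscreen))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1]
}
config_path <- get_arg("--config")
if (is.null(config_path)) {
  message("usage: Rscript scripts/run_pipeline.R --config <run.yaml> [--out <dir>]")
  quit(status = 2)
}

cfg <- tryCatch(validate_config(config_path), error = function(e) {
  message("configuration error: ", conditionMessage(e))
  quit(status = 2)
})
out <- get_arg("--out")
if (!is.null(out)) cfg$output_dir <- out

res <- tryCatch(run_pipeline(cfg), error = function(e) {
  message(conditionMessage(e))
  quit(status = 1)
})
print(res)
if (!is.null(cfg$output_dir))
  message("results written to ", cfg$output_dir)
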