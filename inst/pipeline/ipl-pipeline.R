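#!/usr/bin/env Rscript
# Thin command-line wrapper over iplparc::run_pipeline().
# Usage:
#   Rscript ipl-pipeline.R <stage> --out DIR [--config FILE] [--seed N]
# where <stage> is one of: simulate, parcellate, classify, connectivity,
# ecperm, all.

suppressPackageStartupMessages({
  library(optparse)
  library(iplparc)
})

parser <- OptionParser(
  usage = "%prog <simulate|parcellate|classify|connectivity|ecperm|all> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML configuration file [default: package defaults]"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the master seed"),
    make_option("--out", type = "character", default = "ipl_out",
                help = "output directory [default: %default]"),
    make_option("--log-level", type = "character", default = "info",
                help = "info or quiet [default: %default]")
  )
)
args <- parse_args(parser, positional_arguments = 1L)
stage <- args$args

config <- if (!is.null(args$options$config)) {
  read_config(args$options$config)
} else {
  validate_config(NULL)
}
if (!is.null(args$options$seed)) config$seed <- args$options$seed

run <- function() run_pipeline(config, out_dir = args$options$out,
                               stages = if (stage == "all") "all" else stage)
if (identical(args$options$`log-level`, "quiet")) {
  suppressMessages(invisible(run()))
} else {
  manifest <- run()
  cat("stages completed:", paste(names(manifest$timing), collapse = ", "), "\n")
  cat("outputs in:", normalizePath(args$options$out), "\n")
}
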