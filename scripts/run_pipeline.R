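#!/usr/bin/env Rscript
# Thin command-line wrapper over wssmetrics::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed N] [--out dir]
#
# CLI flags override config-file keys.

suppressMessages({
  library(optparse)
  library(wssmetrics)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON pipeline configuration"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL,
              help = "output directory")
)))

over <- list()
if (!is.null(opts$seed)) over$seed <- opts$seed
if (!is.null(opts$out)) over$out_dir <- opts$out
cfg <- if (is.null(opts$config)) {
  do.call(pipeline_config, over)
} else {
  do.call(read_pipeline_config, c(list(opts$config), over))
}

res <- run_pipeline(cfg)
cat("pipeline complete:", nrow(res$study_table), "animals ->", cfg$out_dir, "\n")
print(res$correlations[, c("x", "y", "r", "p_value")])
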