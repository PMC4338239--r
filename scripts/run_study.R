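#!/usr/bin/env Rscript
# Thin command-line wrapper over the study drivers.
#
# Usage:
#   Rscript scripts/run_study.R --study phantom  --seed 1 --out-dir results/phantom
#   Rscript scripts/run_study.R --study infant   --seed 1 --out-dir results/infant
#   Rscript scripts/run_study.R --config my_study.yaml --out-dir results/custom

suppressMessages(library(adiposim))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

config_path <- get_opt("--config")
study <- get_opt("--study", "phantom")
seed <- as.integer(get_opt("--seed", "1"))
out_dir <- get_opt("--out-dir", "results")

cfg <- if (!is.null(config_path)) {
  read_experiment_config(config_path)
} else if (study == "phantom") {
  experiment_config(study = "phantom_accuracy", seed = seed)
} else if (study == "infant") {
  experiment_config(study = "infant_reproducibility", seed = seed)
} else {
  stop("--study must be 'phantom' or 'infant' (or pass --config).")
}
cfg$out_dir <- out_dir

res <- if (cfg$study == "phantom_accuracy") {
  run_phantom_accuracy(cfg)
} else {
  run_infant_reproducibility(cfg)
}
print(res)
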