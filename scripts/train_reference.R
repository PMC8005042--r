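#!/usr/bin/env Rscript
# Trains and evaluates the three composite architectures on a real
# compounds CSV (e.g. the 532 DHODH inhibitors exported from ChEMBL)
# and writes seed-averaged train/test metrics.
#
# Usage: Rscript scripts/train_reference.R --data compounds.csv \
#          --out metrics.json [--seeds 1,2,3]

suppressPackageStartupMessages({
  library(optparse)
  library(multignn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character"),
  make_option("--out", type = "character", default = "results/reference_metrics.json"),
  make_option("--seeds", type = "character", default = "1,2,3")
)))
if (is.null(opts$data)) stop("--data is required")

seeds <- as.integer(strsplit(opts$seeds, ",")[[1]])
res <- benchmark_architectures(opts$data, seeds = seeds, out = opts$out)
print(res[is.na(res$seed), ])
cat("wrote", opts$out, "\n")
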