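#!/usr/bin/env Rscript
# Thin command-line wrapper over imtx::run_pipeline() for synthetic runs.
#   Rscript scripts/run_pipeline.R --seed 1 --out results/run1 \
#       [--n-genes 500] [--n-surrogates 1000] [--gene-p]

suppressPackageStartupMessages({
  library(optparse)
  library(imtx)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/pipeline"),
  make_option("--n-genes", type = "integer", default = 500L, dest = "n_genes"),
  make_option("--n-surrogates", type = "integer", default = 1000L,
              dest = "n_surrogates"),
  make_option("--n-nulls-gcea", type = "integer", default = 1000L,
              dest = "n_nulls_gcea"),
  make_option("--gene-p", action = "store_true", default = FALSE,
              dest = "gene_p",
              help = "compute per-gene surrogate p-values (slow)")
)))

cfg <- pipeline_config(
  synthetic = synthetic_config(n_genes = opts$n_genes, seed = opts$seed),
  n_surrogates = opts$n_surrogates,
  n_nulls_gcea = opts$n_nulls_gcea,
  compute_gene_p = opts$gene_p,
  seed = opts$seed,
  out_dir = opts$out
)
bundle <- run_pipeline(cfg)
cat("outputs written to", opts$out, "\n")
print(regulon_grid(bundle, "paradigm1"))
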