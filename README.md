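# imtx — imaging transcriptomics with spatially constrained null models

`imtx` relates whole-brain gene-expression maps to task-fMRI activation
maps. Given one expression profile per gene and an activation map over the
same brain regions, it ranks every gene by the Spearman correlation between
its spatial expression pattern and the activation pattern, separately within
the cortex and the subcortex, and then asks what those ranked lists mean:
which annotation categories are enriched, whether a pre-defined risk-gene
set aggregates at the top or bottom of the list, which transcription-factor
regulons are over-represented among the strongly correlated genes, and how
well two ranked lists (two tasks, or two parcellations of the same data)
agree.

The statistical core is inference that respects spatial autocorrelation.
Brain maps carry far fewer effective degrees of freedom than they have
regions, so naive permutation p-values are badly anti-conservative. For a
map `x` over regions with centroid distances `d_ij`, `imtx` builds
variogram-matched surrogate maps: random maps whose semivariogram

γ(h) = ½ · mean[(x_i − x_j)² : d_ij ≈ h]

matches the empirical one. Each surrogate is a permutation of the map,
smoothed over each region's k nearest neighbours (k = 20 cortex / 5
subcortex by convention) at the best of 25 candidate scales, with amplitude
and noise variance fitted by least squares to the empirical variogram. The
two-sided spatial p-value of an observed correlation is the proportion of
surrogates whose absolute correlation exceeds it.

Downstream layers:

* **RRHO** — rank–rank hypergeometric overlap maps between two ranked
  lists, with a scalar rank-agreement coefficient `rho_rrho`.
* **GCEA** — gene-category enrichment: category mean gene scores tested
  against an ensemble of surrogate activation maps (all gene correlations
  recomputed per null map), Benjamini–Hochberg corrected.
* **GSEA** — weighted Kolmogorov–Smirnov enrichment of a risk-gene set:
  running sum with |ρ|-weighted increments, maximum deviation from zero,
  permutation p.
* **Master regulators** — per-motif recovery AUC of the large-effect
  (|ρ| > 0.5) gene sets, z-scored across the motif database into NES;
  regulators with NES > 3 intersected with the risk list and reported as
  `regulator (n_targets/n_possible)`.

Everything runs on synthetic data with planted ground truth — spatially
autocorrelated expression fields, an activation map mixed from a planted
gene program, a toy ontology with one enriched category, and a toy regulon
database with one planted master regulator — so the full pipeline is
testable end to end without any external download. See the methods
vignette (`vignettes/imaging-transcriptomics-methods.Rmd`) for the models,
defaults, and design choices.

## Worked example

```r
library(imtx)

cfg <- synthetic_config(seed = 42)        # 500 genes, 100 + 30 regions
ds  <- generate_dataset(cfg, paradigms = 2)

act <- subset_compartment(ds$activations$paradigm1, "cortex")
tab <- correlate_genes(ds$expression, act)
head(tab, 5)
#>   gene_id    rho p_spatial rank
#> 1   G0435 0.9310        NA    1
#> 2   G0318 0.9251        NA    2
#> 3   G0329 0.9231        NA    3
#> 4   G0091 0.9192        NA    4
#> 5   G0249 0.9192        NA    5
```

All five top genes are members of the planted program (50 genes mixed into
the activation map with weight 0.9); every planted gene passes the
large-effect threshold:

```r
sets <- threshold_correlations(tab, 0.5)
mean(ds$ground_truth$paradigm1$planted_gene_ids %in% sets$positive)
#> [1] 1
```

Category enrichment against surrogate activation maps puts the planted
category first (10 annotated genes, 8 planted):

```r
enr <- gcea(gene_scores(tab, "positive"), ds$annotations, act,
            ds$expression, n_nulls = 500, seed = 7)
head(enr, 3)
#>   category_id n_annotated mean_gene_score p_raw    p_cor
#> 1      CAT006          10          0.7303     0 0.002632
#> 2      CAT018           6          0.3586     0 0.002632
#> 3      CAT024          32          0.2827     0 0.002632
ds$ground_truth$paradigm1$planted_category_id
#> [1] "CAT006"
```

The 42-gene risk list (which contains most of the planted program)
aggregates at the top of the ranked list, and the planted regulator G0275
is recovered with 25 of its targets among the 50 large-effect genes:

```r
gsea_pvalue(tab, intersect(ds$risk_genes, tab$gene_id),
            n_perm = 1000, seed = 7)[c("es", "p")]
#> $es [1] 0.921   $p [1] 0
master_regulators(tab, ds$regulon_db, ds$risk_genes)$grid[["positive"]]
#> [1] "G0275 (25/50)"
```

The second paradigm is planted on a disjoint gene set and its ranked list
barely overlaps the first (`rho_rrho` = 0.162 here), while re-parcellating
the same maps with a different atlas leaves the ranking nearly unchanged —
the contrast the ranked-list comparison layer exists to demonstrate.

`run_pipeline(pipeline_config(...))` chains all stages and writes TSV/JSON
outputs stamped with a configuration hash; two runs with the same seed are
byte-identical. A command-line wrapper is in `scripts/run_pipeline.R`.

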