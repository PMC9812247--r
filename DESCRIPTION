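Package: imtx
Title: Imaging Transcriptomics with Spatially Constrained Null Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Spatial association of whole-brain gene-expression maps with
    task-fMRI activation maps. Computes per-gene Spearman correlations
    voxel-wise and region-wise within cortical and subcortical compartments,
    corrects inference for spatial autocorrelation with variogram-matched
    surrogate maps, compares ranked gene lists by rank-rank hypergeometric
    overlap, performs gene-category enrichment against ensemble nulls and
    weighted Kolmogorov-Smirnov gene-set enrichment of a risk-gene set, and
    nominates master regulators from motif-ranking databases via recovery-AUC
    normalized enrichment scores. Includes a synthetic-data generator with
    planted gene-activation associations so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
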