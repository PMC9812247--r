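# shared fixtures, built in code: a small synthetic brain and a GRF sampler

small_config <- function(seed = 1L, n_genes = 60, ...) {
  synthetic_config(n_genes = n_genes, n_regions_cortex = 20,
                   n_regions_subcortex = 6, grid_shape = c(8, 8, 8),
                   category_size_range = c(4, 12),
                   ..., seed = seed)
}

small_dataset <- function(seed = 1L, ...) {
  generate_dataset(small_config(seed = seed, ...))
}

# exponential-covariance Gaussian random field over given coordinates
grf_sampler <- function(dmat, lambda) {
  L <- chol(exp(-dmat / lambda) + 1e-8 * diag(nrow(dmat)))
  function() as.numeric(rnorm(nrow(dmat)) %*% L)
}

cortex_geometry <- function(seed = 1L, n_cortex = 20) {
  cfg <- synthetic_config(n_regions_cortex = n_cortex,
                          n_regions_subcortex = 4,
                          grid_shape = c(10, 10, 10), seed = seed)
  atlas <- generate_atlas(cfg)
  reg <- atlas$regions[atlas$regions$compartment == "cortex", ]
  as.matrix(dist(as.matrix(reg[, c("x", "y", "z")])))
}

# build a correlation_table directly from a named rho vector (descending)
table_from_rhos <- function(rhos, n_units = 50) {
  ord <- order(-rhos, names(rhos))
  structure(data.frame(gene_id = names(rhos)[ord], rho = rhos[ord],
                       p_spatial = NA_real_, rank = seq_along(rhos),
                       stringsAsFactors = FALSE, row.names = NULL),
            compartment = "cortex", granularity = "region",
            n_units = n_units,
            class = c("correlation_table", "data.frame"))
}
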