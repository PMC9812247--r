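test_that("atlas construction labels every voxel with nonempty parcels", {
  cfg <- synthetic_config(n_regions_cortex = 2, n_regions_subcortex = 2,
                          grid_shape = c(6, 6, 6), n_genes = 10,
                          category_size_range = c(2, 5),
                          planted_gene_fraction = 0.1)
  atlas <- generate_atlas(cfg)
  expect_equal(nrow(atlas$regions), 4)
  expect_true(all(atlas$labels %in% atlas$regions$region_id))
  expect_true(all(atlas$regions$n_voxels >= 1))
  # centroids inside the grid (mm)
  lim <- cfg$grid_shape * cfg$voxel_size_mm
  expect_true(all(atlas$regions$x > 0 & atlas$regions$x < lim[1]))
  expect_true(all(atlas$regions$z > 0 & atlas$regions$z < lim[3]))
  # determinism
  expect_identical(atlas$labels, generate_atlas(cfg)$labels)
})

test_that("atlas generation refuses a grid smaller than the region count", {
  cfg <- synthetic_config(n_regions_cortex = 400, n_regions_subcortex = 100,
                          grid_shape = c(4, 4, 4))
  expect_error(generate_atlas(cfg), "too small")
})

test_that("expression fields are spatially autocorrelated and deterministic", {
  cfg <- synthetic_config(n_genes = 200, n_regions_cortex = 30,
                          n_regions_subcortex = 4, grid_shape = c(10, 10, 10),
                          correlation_length = 30, planted_gene_fraction = 0,
                          seed = 5)
  atlas <- generate_atlas(cfg)
  E <- generate_expression(cfg, atlas)
  expect_true(all(is.finite(E)))
  expect_identical(E, generate_expression(cfg, atlas))

  # near regions more correlated than far regions, Monte Carlo over 200 genes
  reg <- atlas$regions
  D <- as.matrix(dist(as.matrix(reg[, c("x", "y", "z")])))
  C <- cor(E)
  ut <- upper.tri(D)
  near <- D[ut] < quantile(D[ut], 0.2)
  far <- D[ut] > quantile(D[ut], 0.8)
  expect_gt(mean(C[ut][near]), mean(C[ut][far]) + 0.2)
})

test_that("short correlation length gives a flat variogram at the sill", {
  cfg <- synthetic_config(n_genes = 300, n_regions_cortex = 40,
                          n_regions_subcortex = 4, grid_shape = c(10, 10, 10),
                          correlation_length = 1e-6,
                          planted_gene_fraction = 0, seed = 2)
  atlas <- generate_atlas(cfg)
  E <- generate_expression(cfg, atlas)
  reg <- atlas$regions[atlas$regions$compartment == "cortex", ]
  D <- as.matrix(dist(as.matrix(reg[, c("x", "y", "z")])))
  cols <- as.character(reg$region_id)
  gam <- sapply(1:300, function(i)
    compute_variogram(E[i, cols], D, n_lags = 5)$gamma)
  # iid limit: every lag sits at the sill (= field variance 1)
  expect_true(all(abs(rowMeans(gam) - 1) < 0.1))
})

test_that("activation with full effect and one planted gene is that gene", {
  cfg <- small_config(noise_sd = 0, planted_effect = 1,
                      planted_gene_fraction = 1 / 60, planted_gene_cor = 0.99)
  atlas <- generate_atlas(cfg)
  E <- generate_expression(cfg, atlas)
  a <- generate_activation(cfg, E, atlas)
  g <- a$ground_truth$planted_gene_ids
  expect_length(g, 1)
  expect_equal(spearman_cor(a$activation$value, E[g, ]), 1.0)
})

test_that("unplanted activation gives planted genes no advantage", {
  # planted_effect = 0: |rho| of planted vs non-planted indistinguishable
  rho_gap <- replicate(10, {
    cfg <- small_config(seed = sample.int(1e6, 1), planted_effect = 0)
    ds <- generate_dataset(cfg, paradigms = 1)
    act <- subset_compartment(ds$activations$paradigm1, "cortex")
    tab <- correlate_genes(ds$expression, act)
    pl <- tab$gene_id %in% ds$ground_truth$paradigm1$planted_gene_ids
    mean(abs(tab$rho[pl])) - mean(abs(tab$rho[!pl]))
  })
  expect_lt(abs(mean(rho_gap)), 0.1)
})

test_that("planted genes out-correlate the rest under the default effect", {
  gaps <- sapply(1:20, function(s) {
    cfg <- small_config(seed = s, planted_effect = 0.8, noise_sd = 0.2)
    ds <- generate_dataset(cfg, paradigms = 1)
    act <- subset_compartment(ds$activations$paradigm1, "cortex")
    tab <- correlate_genes(ds$expression, act)
    pl <- tab$gene_id %in% ds$ground_truth$paradigm1$planted_gene_ids
    mean(abs(tab$rho[pl])) - mean(abs(tab$rho[!pl]))
  })
  expect_true(all(gaps > 0))
})

test_that("annotations carry the planted structure", {
  ds <- small_dataset(seed = 3)
  gt <- ds$ground_truth$paradigm1
  planted <- gt$planted_gene_ids
  jac <- vapply(ds$annotations, function(g)
    length(intersect(g, planted)) / length(union(g, planted)), numeric(1))
  expect_equal(names(which.max(jac)), gt$planted_category_id)
  expect_true(all(jac[names(jac) != gt$planted_category_id] <
                    jac[gt$planted_category_id]))
  # every motif ranking is a complete tie-free permutation
  expect_true(all(apply(ds$regulon_db$ranks, 1,
                        function(r) identical(unname(sort(r)), seq_along(r)))))
  expect_true(gt$planted_regulator_id %in% ds$risk_genes)
  # non-planted motifs rank planted genes uniformly on average
  pm <- which(ds$regulon_db$motifs$regulator_gene == gt$planted_regulator_id)
  null_ranks <- ds$regulon_db$ranks[-pm, planted, drop = FALSE]
  expect_lt(abs(mean(null_ranks) - (ncol(ds$regulon_db$ranks) + 1) / 2), 2.5)
})
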