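#' Configuration for the synthetic imaging-transcriptomics dataset
#'
#' Defines the study conditions the generator emulates: a voxel lattice split
#' into cortical and subcortical compartments, spatially autocorrelated
#' gene-expression fields with an exponential covariance, an activation map
#' built from a planted subset of genes, and toy annotation/regulon resources
#' carrying one enriched category and one master regulator.
#'
#' Planted genes share a latent spatial field with mixing weight
#' `planted_gene_cor`, so each planted gene individually correlates with the
#' activation map (a prerequisite for recovering them at a large-effect-size
#' threshold); non-planted genes are independent fields.
#'
#' @param n_genes number of genes in the universe.
#' @param n_regions_cortex,n_regions_subcortex parcel counts per compartment
#'   (both must be at least 2).
#' @param grid_shape integer triple, voxel lattice dimensions.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param correlation_length length scale (mm) of the exponential spatial
#'   covariance `exp(-d / correlation_length)`.
#' @param planted_gene_fraction fraction of genes planted per paradigm, in
#'   (0, 0.5] (two disjoint planted sets are reserved, one per paradigm).
#' @param planted_effect mixing weight in \[0, 1\] of the planted-gene signal
#'   in the activation map.
#' @param noise_sd standard deviation of white noise added to the activation.
#' @param planted_gene_cor shared-latent mixing weight in (0, 1) among planted
#'   genes (squared-correlation scale).
#' @param n_categories number of annotation categories.
#' @param category_size_range integer pair, inclusive bounds on category size.
#' @param n_motifs number of motifs in the regulon database.
#' @param seed integer seed; all outputs are pure functions of (config, seed).
#' @return an object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 50, n_regions_cortex = 10,
#'                         n_regions_subcortex = 4, grid_shape = c(8, 8, 8))
synthetic_config <- function(n_genes = 500,
                             n_regions_cortex = 100,
                             n_regions_subcortex = 30,
                             grid_shape = c(16, 16, 16),
                             voxel_size_mm = 2,
                             correlation_length = 10,
                             planted_gene_fraction = 0.1,
                             planted_effect = 0.9,
                             noise_sd = 0.2,
                             planted_gene_cor = 0.8,
                             n_categories = 50,
                             category_size_range = c(5, 50),
                             n_motifs = 100,
                             seed = 1L) {
  if (!is_count(n_genes)) stop_imtx("n_genes must be a positive integer")
  if (!is_count(n_regions_cortex) || n_regions_cortex < 2)
    stop_imtx("n_regions_cortex must be an integer >= 2")
  if (!is_count(n_regions_subcortex) || n_regions_subcortex < 2)
    stop_imtx("n_regions_subcortex must be an integer >= 2")
  if (length(grid_shape) != 3L || !all(vapply(grid_shape, is_count, TRUE)))
    stop_imtx("grid_shape must be three positive integers")
  if (voxel_size_mm <= 0) stop_imtx("voxel_size_mm must be positive")
  if (!is.numeric(correlation_length) || correlation_length <= 0)
    stop_imtx("correlation_length must be positive")
  if (planted_gene_fraction < 0 || planted_gene_fraction > 0.5)
    stop_imtx("planted_gene_fraction must lie in [0, 0.5]")
  if (planted_effect < 0 || planted_effect > 1)
    stop_imtx("planted_effect must lie in [0, 1]")
  if (noise_sd < 0) stop_imtx("noise_sd must be nonnegative")
  if (planted_gene_cor <= 0 || planted_gene_cor >= 1)
    stop_imtx("planted_gene_cor must lie in (0, 1)")
  if (!is_count(n_categories)) stop_imtx("n_categories must be positive")
  if (length(category_size_range) != 2L ||
      category_size_range[1] < 2 ||
      category_size_range[2] > n_genes ||
      category_size_range[1] > category_size_range[2])
    stop_imtx("category_size_range must lie within [2, n_genes]")
  if (!is_count(n_motifs)) stop_imtx("n_motifs must be positive")
  structure(list(
    n_genes = as.integer(n_genes),
    n_regions_cortex = as.integer(n_regions_cortex),
    n_regions_subcortex = as.integer(n_regions_subcortex),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    correlation_length = correlation_length,
    planted_gene_fraction = planted_gene_fraction,
    planted_effect = planted_effect,
    noise_sd = noise_sd,
    planted_gene_cor = planted_gene_cor,
    n_categories = as.integer(n_categories),
    category_size_range = as.integer(category_size_range),
    n_motifs = as.integer(n_motifs),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

gene_ids_for <- function(config) sprintf("G%04d", seq_len(config$n_genes))

voxel_mm_coords <- function(config) {
  g <- config$grid_shape
  vs <- config$voxel_size_mm
  idx <- as.matrix(expand.grid(i = seq_len(g[1]), j = seq_len(g[2]),
                               k = seq_len(g[3])))
  (idx - 0.5) * vs
}

#' Generate a labeled parcellation volume
#'
#' Places subcortical parcels in a central core and cortical parcels in the
#' surrounding shell, then assigns every voxel to the nearest seed of its own
#' compartment (Voronoi parcels): every region is nonempty by construction
#' (each seed voxel belongs to its own parcel).
#'
#' @param config a [synthetic_config()].
#' @return an object of class `brain_atlas`: a list with `labels` (3D integer
#'   array, region ids; this generator labels every voxel), `regions` (data
#'   frame with `region_id`, `compartment`, centroid `x`, `y`, `z` in mm, and
#'   `n_voxels`), and `voxel_size`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid_shape
  V <- prod(g)
  ncx <- config$n_regions_cortex
  nsub <- config$n_regions_subcortex
  ntot <- ncx + nsub
  if (V < ntot)
    stop_imtx("grid too small: %d voxels cannot host %d regions", V, ntot)
  set.seed(substream_seed(config$seed, "atlas"))
  mm <- voxel_mm_coords(config)
  center <- g * config$voxel_size_mm / 2
  r2 <- rowSums(sweep(mm, 2, center)^2)
  ord <- order(r2)
  n_core <- max(nsub, round(V * nsub / ntot))
  core_idx <- ord[seq_len(n_core)]
  shell_idx <- ord[-seq_len(n_core)]
  if (length(shell_idx) < ncx)
    stop_imtx("grid too small: cortical shell has %d voxels for %d regions",
              length(shell_idx), ncx)
  seeds_cx <- sample(shell_idx, ncx)
  seeds_sub <- sample(core_idx, nsub)

  nearest_seed <- function(vox_idx, seed_idx) {
    P <- mm[vox_idx, , drop = FALSE]
    S <- mm[seed_idx, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rep(1, nrow(S))) - 2 * P %*% t(S) +
      outer(rep(1, nrow(P)), rowSums(S^2))
    max.col(-d2, ties.method = "first")
  }
  labels <- integer(V)
  labels[shell_idx] <- nearest_seed(shell_idx, seeds_cx)
  labels[core_idx] <- ncx + nearest_seed(core_idx, seeds_sub)
  labels <- array(labels, dim = g)

  ids <- seq_len(ntot)
  cent <- t(vapply(ids, function(id) colMeans(mm[which(labels == id), ,
                                                 drop = FALSE]),
                   numeric(3)))
  regions <- data.frame(
    region_id = ids,
    compartment = c(rep("cortex", ncx), rep("subcortex", nsub)),
    x = cent[, 1], y = cent[, 2], z = cent[, 3],
    n_voxels = as.integer(tabulate(labels, nbins = ntot)),
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels,
                 regions = regions,
                 voxel_size = rep(config$voxel_size_mm, 3),
                 config = config),
            class = "brain_atlas")
}

grf_cov <- function(atlas, correlation_length) {
  cent <- as.matrix(atlas$regions[, c("x", "y", "z")])
  D <- as.matrix(dist(cent))
  exp(-D / correlation_length)
}

grf_chol <- function(atlas, correlation_length) {
  C <- grf_cov(atlas, correlation_length)
  chol(C + 1e-8 * diag(nrow(C)))
}

#' Generate a region-level gene-expression matrix
#'
#' Each gene's profile is a zero-mean Gaussian random field over region
#' centroids with covariance `exp(-d / correlation_length)`. Two disjoint
#' planted subsets of genes (one per fMRI-like paradigm) additionally share a
#' latent field with mixing weight `planted_gene_cor`, leaving each gene's
#' marginal distribution unchanged but making the planted block mutually
#' correlated — the structure an activation map can load onto.
#'
#' @param config a [synthetic_config()].
#' @param atlas the matching [generate_atlas()] result.
#' @return genes x regions numeric matrix with gene ids as rownames and
#'   region ids as colnames; attributes `planted_sets` (list of two gene-id
#'   vectors) and `mixing_weights` record the planted structure.
#' @export
generate_expression <- function(config, atlas) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(atlas, "brain_atlas"))
  if (config$correlation_length <= 0)
    stop_imtx("correlation_length must be positive")
  genes <- gene_ids_for(config)
  n_pl <- round(config$planted_gene_fraction * config$n_genes)

  set.seed(substream_seed(config$seed, "planted-genes"))
  pool <- if (n_pl > 0) sample(genes, 2L * n_pl) else character(0)
  planted <- list(pool[seq_len(n_pl)],
                  pool[n_pl + seq_len(n_pl)])

  set.seed(substream_seed(config$seed, "expression"))
  L <- grf_chol(atlas, config$correlation_length)
  n_reg <- nrow(atlas$regions)
  draw <- function(m) matrix(rnorm(m * n_reg), m, n_reg) %*% L
  E <- draw(config$n_genes)
  rownames(E) <- genes
  colnames(E) <- as.character(atlas$regions$region_id)
  w <- config$planted_gene_cor
  mixing <- setNames(numeric(config$n_genes), genes)
  latents <- list()
  for (p in seq_along(planted)) {
    ids <- planted[[p]]
    if (length(ids) == 0) next
    latent <- as.numeric(draw(1))
    if (p > 1) {
      # The paradigms emulate distinct task systems, so the second latent
      # must be spatially unrelated to the first in the analyzed (cortex)
      # compartment under both inner products that matter downstream: the
      # plain one (it sets the cross-paradigm correlation of the planted
      # genes themselves) and the covariance-weighted one (genes are draws
      # from N(0, C), so it sets the across-gene correlation of the two
      # per-gene correlation vectors). Candidate latents are redrawn until
      # both correlations are small; with few effective spatial degrees of
      # freedom a single draw can show chance correlations of +/-0.5.
      latent <- decorrelated_draw(function() as.numeric(draw(1)),
                                  latent, latents[1], atlas,
                                  config$correlation_length)
    }
    latents[[p]] <- latent
    E[ids, ] <- sqrt(w) * matrix(latent, length(ids), n_reg, byrow = TRUE) +
      sqrt(1 - w) * E[ids, , drop = FALSE]
    mixing[ids] <- w
  }
  attr(E, "planted_sets") <- planted
  attr(E, "mixing_weights") <- mixing
  attr(E, "latents") <- latents
  attr(E, "correlation_length") <- config$correlation_length
  E
}

# Redraw a smooth field until it is spatially unrelated, within the cortex,
# to each reference field under both the plain inner product and the
# covariance-weighted one (genes are N(0, C) draws, so the latter governs
# across-gene correlation structure). Capped best-of rejection keeps the
# generator deterministic and always terminating.
decorrelated_draw <- function(draw_fn, first, refs, atlas,
                              correlation_length, threshold = 0.05,
                              max_tries = 500L) {
  cx <- atlas$regions$compartment == "cortex"
  ncx <- sum(cx)
  Cm <- grf_cov(atlas, correlation_length)[cx, cx]
  H <- diag(ncx) - 1 / ncx
  Cc <- H %*% Cm %*% H
  refs_c <- lapply(refs, function(r) r[cx] - mean(r[cx]))
  score <- function(v) {
    vc <- v[cx] - mean(v[cx])
    vC <- as.numeric(Cc %*% vc)
    max(vapply(refs_c, function(rc)
      max(abs(cor(rc, vc)),
          abs(sum(rc * vC) /
                sqrt(sum(rc * (Cc %*% rc)) * sum(vc * vC)))),
      numeric(1)))
  }
  best <- first
  best_score <- score(first)
  tries <- 0L
  while (best_score > threshold && tries < max_tries) {
    cand <- draw_fn()
    sc <- score(cand)
    if (sc < best_score) {
      best <- cand
      best_score <- sc
    }
    tries <- tries + 1L
  }
  best
}

#' Generate an activation map with planted gene associations
#'
#' The region-level activation equals
#' `planted_effect * z(mean of planted genes) +
#'  (1 - planted_effect) * z(independent smooth field) + noise_sd * white`,
#' where `z()` standardizes to unit variance, so `planted_effect` is
#' interpretable on the correlation scale.
#'
#' @param config a [synthetic_config()].
#' @param expression matrix from [generate_expression()].
#' @param atlas the matching atlas.
#' @param paradigm which planted subset to use (1 or 2); the two paradigms
#'   are planted on disjoint gene sets.
#' @return list with `activation` (a region-level [spatial_profile] covering
#'   both compartments) and `ground_truth` (planted gene ids, mixing weights;
#'   category/regulator ids are filled in by [generate_annotations()]).
#' @export
generate_activation <- function(config, expression, atlas, paradigm = 1L) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(atlas, "brain_atlas"),
            paradigm %in% c(1L, 2L))
  planted <- attr(expression, "planted_sets")[[paradigm]]
  if (length(planted) < 1)
    stop_imtx("empty planted gene set: planted_gene_fraction * n_genes < 1")
  set.seed(substream_seed(config$seed, paste0("activation-", paradigm)))
  n_reg <- ncol(expression)
  planted_mean <- colMeans(expression[planted, , drop = FALSE])
  z <- function(v) as.numeric(scale(v))
  L <- grf_chol(atlas, config$correlation_length)
  draw1 <- function() as.numeric(matrix(rnorm(n_reg), 1) %*% L)
  # the unrelated smooth background must not echo either paradigm's latent
  smooth_field <- decorrelated_draw(draw1, draw1(),
                                    attr(expression, "latents"), atlas,
                                    config$correlation_length)
  act <- config$planted_effect * z(planted_mean) +
    (1 - config$planted_effect) * z(smooth_field) +
    config$noise_sd * rnorm(n_reg)
  profile <- spatial_profile(
    unit_ids = colnames(expression),
    values = act,
    coordinates = as.matrix(atlas$regions[, c("x", "y", "z")]),
    compartment = atlas$regions$compartment,
    granularity = "region"
  )
  gt <- list(planted_gene_ids = planted,
             planted_category_id = NA_character_,
             planted_regulator_id = NA_character_,
             true_mixing_weights = attr(expression, "mixing_weights"))
  list(activation = profile, ground_truth = gt)
}


#' Generate toy annotations, a risk-gene list, and a regulon database
#'
#' Categories are random gene sets with sizes drawn from
#' `category_size_range`; exactly one category is seeded predominantly (80%)
#' with planted genes. The regulon database assigns each motif a regulator
#' gene and a complete tie-free ranking of the universe; one planted motif
#' ranks the planted regulator's targets (half of the planted genes) at the
#' top, all other motifs are uniform permutations. The risk list contains the
#' planted regulator plus a majority of planted genes, padded with random
#' genes.
#'
#' @param config a [synthetic_config()].
#' @param ground_truth list from [generate_activation()].
#' @param risk_size size of the risk-gene list (default 42, the size of the
#'   depression GWAS functional risk-gene list this emulates).
#' @return list with `annotations` (named list of gene-id vectors),
#'   `risk_genes`, `regulon_db` (class `regulon_db`), and the completed
#'   `ground_truth` (now including `planted_category_id`,
#'   `planted_regulator_id`, `planted_targets`).
#' @export
generate_annotations <- function(config, ground_truth, risk_size = 42L) {
  stopifnot(inherits(config, "synthetic_config"),
            is.list(ground_truth))
  genes <- gene_ids_for(config)
  planted <- ground_truth$planted_gene_ids
  rng <- config$category_size_range
  if (rng[1] > config$n_genes)
    stop_imtx("category_size_range infeasible for %d genes", config$n_genes)
  set.seed(substream_seed(config$seed, "annotations"))
  sizes <- sample(seq(rng[1], rng[2]), config$n_categories, replace = TRUE)
  planted_idx <- sample(config$n_categories, 1)

  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  make_planted_cat <- function(size) {
    n_from <- min(length(planted), ceiling(0.8 * size))
    c(sample(planted, n_from),
      sample(setdiff(genes, planted), size - n_from))
  }
  cats <- vector("list", config$n_categories)
  for (i in seq_len(config$n_categories)) {
    cats[[i]] <- if (i == planted_idx) make_planted_cat(sizes[i])
                 else sample(genes, sizes[i])
  }
  # construction guarantee: no random category may tie or beat the planted one
  j_planted <- jaccard(cats[[planted_idx]], planted)
  for (i in seq_len(config$n_categories)) {
    if (i == planted_idx) next
    while (jaccard(cats[[i]], planted) >= j_planted) {
      cats[[i]] <- sample(genes, sizes[i])
    }
  }
  names(cats) <- sprintf("CAT%03d", seq_len(config$n_categories))

  regulator <- sample(setdiff(genes, planted), 1)
  n_targets <- max(1L, length(planted) %/% 2L)
  targets <- sample(planted, n_targets)

  ranks <- matrix(0L, config$n_motifs, config$n_genes,
                  dimnames = list(sprintf("M%03d", seq_len(config$n_motifs)),
                                  genes))
  planted_motif <- sample(config$n_motifs, 1)
  regulators <- sample(genes, config$n_motifs, replace = TRUE)
  regulators[planted_motif] <- regulator
  for (m in seq_len(config$n_motifs)) {
    if (m == planted_motif) {
      top <- sample(targets)
      rest <- sample(setdiff(genes, targets))
      ranks[m, c(top, rest)] <- seq_len(config$n_genes)
    } else {
      ranks[m, sample(genes)] <- seq_len(config$n_genes)
    }
  }
  db <- structure(list(
    motifs = data.frame(motif_id = rownames(ranks),
                        regulator_gene = regulators,
                        stringsAsFactors = FALSE),
    ranks = ranks
  ), class = "regulon_db")

  n_pl_risk <- min(30L, length(planted), risk_size - 1L)
  risk <- unique(c(regulator, sample(planted, n_pl_risk)))
  pad <- setdiff(genes, risk)
  risk <- c(risk, sample(pad, max(0L, risk_size - length(risk))))

  ground_truth$planted_category_id <- names(cats)[planted_idx]
  ground_truth$planted_regulator_id <- regulator
  ground_truth$planted_targets <- targets
  list(annotations = cats,
       risk_genes = risk,
       regulon_db = db,
       ground_truth = ground_truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_atlas()], [generate_expression()],
#' [generate_activation()] (one or two paradigms on disjoint planted sets),
#' and [generate_annotations()].
#'
#' @param config a [synthetic_config()].
#' @param paradigms how many activation maps to generate (1 or 2).
#' @return list with `atlas`, `expression`, `activations` (named list of
#'   spatial profiles), `annotations`, `risk_genes`, `regulon_db`, and
#'   `ground_truth` (per paradigm).
#' @export
generate_dataset <- function(config, paradigms = 2L) {
  atlas <- generate_atlas(config)
  expr <- generate_expression(config, atlas)
  acts <- list()
  gts <- list()
  for (p in seq_len(paradigms)) {
    a <- generate_activation(config, expr, atlas, paradigm = p)
    acts[[paste0("paradigm", p)]] <- a$activation
    gts[[paste0("paradigm", p)]] <- a$ground_truth
  }
  # annotations, risk list and regulon database are anchored on paradigm 1
  ann <- generate_annotations(config, gts[[1]])
  gts[[1]] <- ann$ground_truth
  list(atlas = atlas, expression = expr, activations = acts,
       annotations = ann$annotations, risk_genes = ann$risk_genes,
       regulon_db = ann$regulon_db, ground_truth = gts)
}

#' Paint region values into a voxel volume
#'
#' Writes each region's value into its member voxels and adds small
#' region-centered jitter (centered so region means recover the generating
#' values exactly).
#'
#' @param atlas a `brain_atlas`.
#' @param region_values numeric vector named by region id.
#' @param jitter_sd standard deviation of the within-region jitter.
#' @param seed integer seed for the jitter.
#' @return a [brain_volume()].
#' @export
paint_volume <- function(atlas, region_values, jitter_sd = 0.05, seed = 1L) {
  stopifnot(inherits(atlas, "brain_atlas"))
  labels <- atlas$labels
  vals <- array(0, dim = dim(labels))
  set.seed(substream_seed(seed, "paint"))
  for (id in atlas$regions$region_id) {
    idx <- which(labels == id)
    v <- region_values[[as.character(id)]]
    jit <- rnorm(length(idx), sd = jitter_sd)
    vals[idx] <- v + jit - mean(jit)
  }
  brain_volume(vals, voxel_size = atlas$voxel_size)
}
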