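test_that("variogram reproduces closed-form and limit cases", {
  dmat <- cortex_geometry(seed = 2)
  n <- nrow(dmat)
  expect_equal(compute_variogram(rep(3, n), dmat)$gamma,
               rep(0, nrow(compute_variogram(rep(3, n), dmat))))

  # pair with values 0 and 2 alone in its lag bin: gamma = 0.5 * 2^2 = 2
  d3 <- matrix(c(0, 5, 3,
                 5, 0, 4,
                 3, 4, 0), 3, byrow = TRUE)
  v <- compute_variogram(c(0, 2, 1), d3, n_lags = 3, max_frac = 1)
  expect_equal(v$gamma[v$lag == 5], 2)
  expect_equal(v$n_pairs, c(1L, 1L, 1L))

  # iid standard normal: sill = variance = 1 at every lag
  set.seed(7)
  big <- cortex_geometry(seed = 3, n_cortex = 200)
  gam <- replicate(30, compute_variogram(rnorm(200), big, n_lags = 8)$gamma)
  expect_true(all(abs(rowMeans(gam) - 1) < 3 * 0.05))

  expect_error(compute_variogram(1:4, matrix(0, 4, 4)), "degenerate geometry")
})

test_that("surrogates are deterministic and reject bad k", {
  dmat <- cortex_geometry(seed = 4)
  set.seed(1)
  x <- grf_sampler(dmat, 10)()
  e1 <- generate_surrogates(x, dmat, 5, 10, seed = 3)
  e2 <- generate_surrogates(x, dmat, 5, 10, seed = 3)
  expect_identical(e1$surrogates, e2$surrogates)
  expect_error(generate_surrogates(x, dmat, nrow(dmat), 10), "k_neighbors")
})

test_that("rank-remapped surrogates preserve the source value multiset", {
  dmat <- cortex_geometry(seed = 5)
  set.seed(2)
  x <- grf_sampler(dmat, 10)()
  ens <- generate_surrogates(x, dmat, 10, 20, seed = 4, rank_remap = TRUE)
  sx <- sort(x)
  for (i in 1:20) expect_equal(sort(ens$surrogates[i, ]), sx)
})

test_that("surrogates preserve spatial autocorrelation, permutations do not", {
  # Moran-type statistic: correlation between neighbouring units' values
  dmat <- cortex_geometry(seed = 6, n_cortex = 60)
  W <- (dmat < quantile(dmat[dmat > 0], 0.1)) & dmat > 0
  moran <- function(v) {
    z <- scale(v)[, 1]
    sum(W * outer(z, z)) / sum(W) / mean(z^2)
  }
  set.seed(3)
  x <- grf_sampler(dmat, 15)()
  m_src <- moran(x)
  ens <- generate_surrogates(x, dmat, 10, 50, seed = 5, rank_remap = TRUE)
  m_sur <- mean(apply(ens$surrogates, 1, moran))
  m_perm <- mean(replicate(50, moran(sample(x))))
  expect_gt(m_src, 0.3)             # the source really is autocorrelated
  expect_lt(m_perm, 0.5 * m_src)    # plain permutation destroys it
  # surrogates stay far closer to the source autocorrelation than
  # permutations do
  expect_lt(abs(m_sur - m_src), 0.5 * abs(m_perm - m_src))
})

test_that("spatial p-values implement the literal strict proportion", {
  expect_equal(spatial_pvalue(0.5, c(0.6, -0.4, 0.3, -0.7)), 0.5)
  expect_equal(spatial_pvalue(0, c(0.1, -0.2, 0.3)), 1.0)
  expect_equal(spatial_pvalue(0.9, c(0.1, 0.2)), 0)
  expect_equal(spatial_pvalue(0.9, c(0.1, 0.2), pseudo_count = TRUE), 1 / 3)
  expect_error(spatial_pvalue(0.5, numeric(0)), "at least one")
  expect_identical(format_spatial_p(0, 1000), "< 0.001")
})

test_that("iid sources give surrogates indistinguishable from permutations", {
  dmat <- cortex_geometry(seed = 7, n_cortex = 40)
  n <- nrow(dmat)
  set.seed(8)
  x <- rnorm(n)       # no spatial structure at all
  ref <- rnorm(n)
  ens <- generate_surrogates(x, dmat, 10, 500, seed = 6, rank_remap = TRUE,
                             ref = ref)
  perm_rho <- replicate(500, cor(ref, sample(x), method = "spearman"))
  ks <- suppressWarnings(stats::ks.test(abs(ens$rho), abs(perm_rho)))
  expect_gt(ks$p.value, 0.01)
})
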