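test_that("gene scores rectify by direction", {
  tab <- table_from_rhos(c(a = 0.865, b = -0.3, c = 0.1))
  expect_equal(gene_scores(tab, "positive")$score[
    gene_scores(tab, "positive")$gene_id == "a"], 0.865)
  pos <- gene_scores(tab, "positive")
  expect_equal(pos$score[pos$gene_id == "b"], 0)
  neg <- gene_scores(tab, "negative")
  expect_equal(neg$score[neg$gene_id == "b"], 0.3)
  expect_equal(sort(gene_scores(tab, "absolute")$score),
               sort(c(0.865, 0.3, 0.1)))
})

test_that("gsea enrichment score matches the hand-stepped example", {
  tab <- table_from_rhos(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  res <- gsea_es(tab, c("g1", "g3"), weight_exponent = 1)
  expect_equal(res$es_curve, c(2 / 3, 1 / 6, 1 / 2, 0), tolerance = 1e-12)
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
  expect_equal(res$max_position, 1L)
})

test_that("gsea boundary behavior: top set, bottom set, degenerate sets", {
  tab <- table_from_rhos(setNames(10:1, sprintf("g%02d", 1:10)))
  top <- tab$gene_id[1:3]
  expect_equal(gsea_es(tab, top)$es, 1.0)
  bottom <- tab$gene_id[8:10]
  expect_lt(gsea_es(tab, bottom)$es, 0)
  expect_error(gsea_es(tab, tab$gene_id), "degenerate")
  expect_error(gsea_es(tab, character(0)), "nonempty")
  expect_error(gsea_es(tab, "nope"), "subset")
})

test_that("unweighted gsea equals the two-sample KS statistic", {
  set.seed(1)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    rho <- setNames(sort(rnorm(N), decreasing = TRUE), sprintf("g%03d", 1:N))
    tab <- table_from_rhos(rho)
    m <- sample(2:(N - 2), 1)
    set <- sample(names(rho), m)
    es <- gsea_es(tab, set, weight_exponent = 0)$es
    # oracle: max signed difference between the two prefix ECDFs
    hit <- tab$gene_id %in% set
    diffs <- cumsum(hit) / m - cumsum(!hit) / (N - m)
    expect_equal(abs(es), max(abs(diffs)), tolerance = 1e-10)
  }
})

test_that("gsea running sum always returns to zero", {
  set.seed(2)
  for (i in 1:20) {
    N <- sample(8:50, 1)
    tab <- table_from_rhos(setNames(rnorm(N), sprintf("g%03d", 1:N)))
    set <- sample(tab$gene_id, sample(2:(N - 1), 1))
    w <- sample(c(0, 0.5, 1, 2), 1)
    expect_equal(gsea_es(tab, set, w)$es_curve[N], 0, tolerance = 1e-12)
  }
})

test_that("gsea permutation p is calibrated and detects planted top sets", {
  set.seed(3)
  tab <- table_from_rhos(setNames(rnorm(100), sprintf("g%03d", 1:100)))
  ps <- replicate(40, {
    gsea_pvalue(tab, sample(tab$gene_id, 10), n_perm = 100,
                seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.3)                # near-uniform null
  strong <- gsea_pvalue(tab, tab$gene_id[1:10], n_perm = 200, seed = 9)
  expect_lt(strong$p, 0.05)
  # p is the literal two-sided proportion against the stored null sample
  expect_equal(strong$p, mean(abs(strong$null_es) >= abs(strong$es)))
})

test_that("benjamini-hochberg adjustment matches the direct oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-10)
  }
})

test_that("gcea finds the planted category and respects the size window", {
  ds <- small_dataset(seed = 11, planted_effect = 0.9, noise_sd = 0.2)
  act <- subset_compartment(ds$activations$paradigm1, "cortex")
  tab <- correlate_genes(ds$expression, act)
  sc <- gene_scores(tab, "positive")
  enr <- gcea(sc, ds$annotations, act, ds$expression, n_nulls = 100,
              seed = 5, size_range = c(2, 200))
  expect_true(all(enr$p_cor >= enr$p_raw - 1e-12))
  expect_identical(enr$category_id[1],
                   ds$ground_truth$paradigm1$planted_category_id)
  expect_lt(enr$p_cor[1], 0.05)

  expect_warning(gcea(sc, ds$annotations, act, ds$expression,
                      n_nulls = 100, seed = 5, size_range = c(190, 200)),
                 "size window")
})

test_that("gcea p-values are insensitive to relabeling unannotated genes", {
  ds <- small_dataset(seed = 12)
  act <- subset_compartment(ds$activations$paradigm1, "cortex")
  tab <- correlate_genes(ds$expression, act)
  sc <- gene_scores(tab, "positive")
  ann <- ds$annotations[1:5]
  e1 <- gcea(sc, ann, act, ds$expression, n_nulls = 100, seed = 7,
             size_range = c(2, 200))
  # permute ids among genes not annotated anywhere: category stats unchanged
  annotated <- unique(unlist(ann))
  free <- setdiff(sc$gene_id, annotated)
  swap <- setNames(sc$gene_id, sc$gene_id)
  swap[free] <- sample(free)
  sc2 <- sc; sc2$gene_id <- unname(swap[sc$gene_id])
  expr2 <- ds$expression
  rownames(expr2) <- unname(swap[rownames(ds$expression)])
  e2 <- gcea(sc2, ann, act, expr2, n_nulls = 100, seed = 7,
             size_range = c(2, 200))
  expect_equal(e1$p_raw, e2$p_raw[match(e1$category_id, e2$category_id)])
})
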