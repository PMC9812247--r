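make_ranking <- function(genes) setNames(sample(seq_along(genes)), genes)

test_that("recovery auc matches its definition on worked cases", {
  genes <- sprintf("g%03d", 1:200)
  r <- setNames(seq_along(genes), genes)           # identity ranking
  # single set gene at rank 1, window R = 10: auc = 1
  expect_equal(recovery_auc(r, "g001", auc_max_fraction = 0.05), 1.0)
  # all set genes beyond the window: auc = 0
  expect_equal(recovery_auc(r, c("g150", "g199"), 0.05), 0)
  expect_error(recovery_auc(r, character(0)), "nonempty")
  expect_error(recovery_auc(r, "g001", 0.5), "auc_max_fraction")

  # oracle: explicit recovery-curve summation on random instances
  set.seed(1)
  for (i in 1:100) {
    rk <- make_ranking(sprintf("g%03d", 1:60))
    set <- sample(names(rk), sample(1:10, 1))
    R <- ceiling(0.1 * 60)
    y <- vapply(1:R, function(x) sum(rk[set] <= x), numeric(1))
    expect_equal(recovery_auc(rk, set, 0.1), sum(y) / (length(set) * R),
                 tolerance = 1e-12)
  }
})

test_that("recovery auc is monotone in rank improvements and matches the
           random-set expectation", {
  set.seed(2)
  rk <- make_ranking(sprintf("g%03d", 1:100))
  set <- sample(names(rk), 8)
  base <- recovery_auc(rk, set, 0.2)
  # move one set gene to the top: auc never decreases
  g <- set[1]
  rk2 <- rk
  better <- names(rk2)[rk2 == 1]
  rk2[c(g, better)] <- rk2[c(better, g)]
  expect_gte(recovery_auc(rk2, set, 0.2), base)

  # E[auc] for a uniformly random singleton set is (R+1)/(2N) within MC error
  aucs <- replicate(1000, recovery_auc(make_ranking(sprintf("g%02d", 1:50)),
                                       "g01", 0.2))
  R <- 10; N <- 50
  expect_equal(mean(aucs), (R + 1) / (2 * N), tolerance = 0.15)
})

test_that("nes is a z-score, affine-invariant, and rejects degeneracy", {
  expect_equal(unname(nes_scores(c(a = 0.1, b = 0.2, c = 0.3))),
               c(-1, 0, 1))
  set.seed(3)
  a <- runif(20)
  expect_equal(nes_scores(a), nes_scores(3 * a + 0.7), tolerance = 1e-12)
  expect_error(nes_scores(rep(0.2, 5)), "degenerate")
  expect_error(nes_scores(c(0.1, 0.2)), "at least 3")
})

test_that("random regulon databases rarely exceed the nes threshold", {
  set.seed(4)
  genes <- sprintf("g%03d", 1:300)
  aucs <- vapply(1:400, function(m)
    recovery_auc(make_ranking(genes), sample(genes, 20), 0.05), numeric(1))
  expect_lt(mean(nes_scores(aucs) > 3), 0.01)
})

test_that("master regulators recover the planted regulator, and only for the
           direction carrying the planted genes", {
  ds <- small_dataset(seed = 21, planted_effect = 0.9, noise_sd = 0.2)
  gt <- ds$ground_truth$paradigm1
  act <- subset_compartment(ds$activations$paradigm1, "cortex")
  tab <- correlate_genes(ds$expression, act)
  rep <- suppressWarnings(
    master_regulators(tab, ds$regulon_db, ds$risk_genes))
  expect_true(gt$planted_regulator_id %in%
                rep$report$regulator_gene[rep$report$direction == "positive"])
  expect_false(gt$planted_regulator_id %in%
                 rep$report$regulator_gene[rep$report$direction == "negative"])
  row <- rep$report[rep$report$regulator_gene == gt$planted_regulator_id, ][1, ]
  expect_gt(row$nes, 3)
  expect_lte(row$n_targets, row$n_possible)
  expect_true(all(strsplit(row$targets, ",")[[1]] %in% tab$gene_id))
  expect_match(rep$grid[["positive"]], "\\(\\d+/\\d+\\)")

  # risk list without the retained regulators empties the report but keeps nes
  rep2 <- suppressWarnings(
    master_regulators(tab, ds$regulon_db, risk_genes = "not_a_gene"))
  expect_equal(NROW(rep2$report), 0)
  expect_gt(NROW(rep2$nes_table), 0)
  expect_identical(unname(rep2$grid), c("-", "-"))
})

test_that("thresholds nobody passes yield empty grid cells with warnings", {
  ds <- small_dataset(seed = 22, planted_effect = 0)
  act <- subset_compartment(ds$activations$paradigm1, "cortex")
  tab <- correlate_genes(ds$expression, act)
  w <- capture_warnings(
    rep <- suppressMessages(
      master_regulators(tab, ds$regulon_db, ds$risk_genes, rho_min = 0.99)))
  expect_match(w, "empty", all = TRUE)
  expect_identical(unname(rep$grid), c("-", "-"))
})
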