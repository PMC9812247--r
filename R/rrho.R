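#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, t1, t2)`: the probability that two
#' random subsets of sizes `t1` and `t2` drawn from a universe of `N` genes
#' share at least `k` members.
#'
#' @param N universe size.
#' @param t1,t2 subset sizes.
#' @param k observed overlap.
#' @return p-value in \[0, 1\]; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_overlap_p(8, 4, 4, 3)  # 17/70
hypergeom_overlap_p <- function(N, t1, t2, k) {
  if (any(c(N, t1, t2, k) < 0) || t1 > N || t2 > N || k > min(t1, t2))
    stop_imtx("infeasible counts: need 0 <= k <= min(t1, t2) <= N")
  phyper(k - 1, t1, N - t1, t2, lower.tail = FALSE)
}

#' Rank-rank hypergeometric overlap of two ranked gene lists
#'
#' For each pair of rank cutoffs `(i * step, j * step)` the overlap between
#' the two lists' top prefixes is scored with the upper-tail hypergeometric
#' p-value; matrix entries are `-log10(p)`, signed positive when the overlap
#' exceeds its expectation `t1 * t2 / N` and negative otherwise. The scalar
#' rank-agreement coefficient `rho_rrho` is the Spearman correlation between
#' the two lists' per-gene ranking metrics (their signed correlation values),
#' with a gene-label permutation p-value.
#'
#' @param list1,list2 [correlate_genes()] tables over identical gene
#'   universes (genes with missing `rho` are excluded from both).
#' @param step rank step between cutoffs; default `max(1, floor(N/100))`
#'   gives a roughly 100 x 100 map at any problem size.
#' @param n_perm permutations for the `rho_rrho` p-value.
#' @param seed integer seed for the permutation null.
#' @return object of class `rrho_result`: list with `signed_logp` matrix,
#'   `thresholds_1`, `thresholds_2`, `step`, `rho_rrho`, `p_rrho`.
#' @export
rrho_map <- function(list1, list2, step = NULL, n_perm = 200, seed = 1L) {
  stopifnot(inherits(list1, "correlation_table"),
            inherits(list2, "correlation_table"))
  g1 <- list1$gene_id[!is.na(list1$rho)]
  g2 <- list2$gene_id[!is.na(list2$rho)]
  if (!setequal(g1, g2))
    stop_imtx("gene universes differ between the two ranked lists")
  genes <- sort(g1)
  N <- length(genes)
  step <- step %||% max(1L, floor(N / 100))
  if (!is_count(step)) stop_imtx("step must be a positive integer")

  rank1 <- setNames(list1$rank[match(genes, list1$gene_id)], genes)
  rank2 <- setNames(list2$rank[match(genes, list2$gene_id)], genes)
  cutoffs <- seq(step, N, by = step)
  nc <- length(cutoffs)

  # 2D cumulative counts of (rank1, rank2) points at the cutoff grid;
  # genes ranked beyond the last cutoff on either axis never enter a prefix
  b1 <- ceiling(rank1 / step)
  b2 <- ceiling(rank2 / step)
  keep <- b1 <= nc & b2 <= nc
  H <- matrix(0L, nc, nc)
  for (i in which(keep)) H[b1[i], b2[i]] <- H[b1[i], b2[i]] + 1L
  overlap <- t(apply(apply(H, 2, cumsum), 1, cumsum))
  # overlap[i, j] = |top_{c_i}(list1) intersect top_{c_j}(list2)|

  t1 <- matrix(cutoffs, nc, nc)
  t2 <- t(t1)
  p <- phyper(overlap - 1, t1, N - t1, t2, lower.tail = FALSE)
  expect <- t1 * t2 / N
  signed_logp <- sign(overlap - expect) * (-log10(pmax(p, 1e-320)))

  rho1 <- setNames(list1$rho[match(genes, list1$gene_id)], genes)
  rho2 <- setNames(list2$rho[match(genes, list2$gene_id)], genes)
  rho_rrho <- spearman_cor(rho1, rho2)
  set.seed(substream_seed(seed, "rrho-perm"))
  null_rho <- replicate(n_perm, spearman_cor(rho1, sample(rho2)))
  p_rrho <- mean(abs(null_rho) >= abs(rho_rrho))

  structure(list(signed_logp = signed_logp,
                 thresholds_1 = cutoffs, thresholds_2 = cutoffs,
                 step = as.integer(step),
                 rho_rrho = rho_rrho, p_rrho = p_rrho),
            class = "rrho_result")
}
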