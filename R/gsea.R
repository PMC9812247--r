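#' Gene-level scores from a ranked correlation table
#'
#' Transforms per-gene correlations into nonnegative gene scores for category
#' enrichment: positively and negatively associated gene programs are scored
#' separately (one-sided rectification), with an absolute mode available.
#'
#' @param table a [correlate_genes()] result.
#' @param direction `"positive"` (`max(rho, 0)`), `"negative"`
#'   (`max(-rho, 0)`), or `"absolute"` (`|rho|`).
#' @return data frame of class `gene_score_table` with columns `gene_id`,
#'   `score`; attribute `direction`. Genes with missing `rho` are dropped.
#' @export
gene_scores <- function(table,
                        direction = c("positive", "negative", "absolute")) {
  stopifnot(inherits(table, "correlation_table"))
  direction <- match.arg(direction)
  ok <- !is.na(table$rho)
  rho <- table$rho[ok]
  score <- switch(direction,
                  positive = pmax(rho, 0),
                  negative = pmax(-rho, 0),
                  absolute = abs(rho))
  structure(data.frame(gene_id = table$gene_id[ok], score = score,
                       stringsAsFactors = FALSE),
            direction = direction,
            class = c("gene_score_table", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the list ranked by descending correlation; on gene-set members the
#' running sum increases by `|rho|^w / sum_set(|rho|^w)`, on non-members it
#' decreases by `1 / (N - |set|)`. The enrichment score is the signed value
#' of the running sum at its maximum absolute deviation from zero. With
#' `w = 0` this is the classic unweighted KS statistic. The running sum ends
#' at exactly zero (both cumulative distributions reach 1); this conservation
#' is checked on every call.
#'
#' @param table a [correlate_genes()] result (or any table ranked by a
#'   per-gene metric in `rho`).
#' @param gene_set character vector, a nonempty proper subset of the ranked
#'   universe.
#' @param weight_exponent weight `w >= 0` applied to `|rho|` (default 1).
#' @return object of class `gsea_result`: list with `es`, `es_curve`,
#'   `max_position`, `p` (NA until [gsea_pvalue()]).
#' @export
gsea_es <- function(table, gene_set, weight_exponent = 1) {
  stopifnot(inherits(table, "correlation_table"))
  ok <- !is.na(table$rho)
  genes <- table$gene_id[ok]
  rho <- table$rho[ok]
  N <- length(genes)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0 || !all(gene_set %in% genes))
    stop_imtx("gene set must be a nonempty subset of the ranked universe")
  m <- length(gene_set)
  if (m >= N) stop_imtx("degenerate set: equals the whole universe")
  hit <- genes %in% gene_set
  wts <- abs(rho[hit])^weight_exponent
  inc <- if (sum(wts) > 0) wts / sum(wts) else rep(1 / m, m)
  steps <- numeric(N)
  steps[hit] <- inc
  steps[!hit] <- -1 / (N - m)
  curve <- cumsum(steps)
  if (abs(curve[N]) > 1e-9)
    stop_imtx("internal error: running sum does not return to zero")
  pos <- which.max(abs(curve))
  structure(list(es = curve[pos], es_curve = curve,
                 max_position = pos, p = NA_real_),
            class = "gsea_result")
}

#' Permutation p-value for a gene-set enrichment score
#'
#' The null distribution is formed by re-drawing random gene sets of the same
#' size from the ranked universe; the two-sided p-value is the proportion of
#' null scores whose absolute value reaches the observed one. No multiple-
#' testing adjustment is applied (intended for a single pre-defined set).
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return a `gsea_result` with `p` filled and `null_es` attached.
#' @export
gsea_pvalue <- function(table, gene_set, weight_exponent = 1,
                        n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop_imtx("n_perm must be at least 100")
  obs <- gsea_es(table, gene_set, weight_exponent)
  genes <- table$gene_id[!is.na(table$rho)]
  m <- length(unique(gene_set))
  set.seed(substream_seed(seed, "gsea-perm"))
  null_es <- vapply(seq_len(n_perm), function(b) {
    gsea_es(table, sample(genes, m), weight_exponent)$es
  }, numeric(1))
  obs$p <- mean(abs(null_es) >= abs(obs$es))
  obs$null_es <- null_es
  obs
}
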