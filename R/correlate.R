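#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks on ties). Spearman is used
#' throughout the package because regional mRNA values are partly
#' non-symmetrically distributed and contain outliers; a rank statistic is
#' robust to both and invariant to monotone transforms.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @return correlation in \[-1, 1\].
#' @export
#' @examples
#' spearman_cor(1:3, c(1, 4, 9))   # 1: monotone
#' spearman_cor(1:3, 3:1)          # -1: antitone
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_imtx("x and y must have equal length")
  if (length(x) < 3) stop_imtx("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_imtx("inputs must be finite")
  if (max(x) == min(x) || max(y) == min(y))
    stop_imtx("undefined correlation: constant input vector")
  cor(rank(x), rank(y))
}

#' Correlate every gene's expression profile with an activation profile
#'
#' Computes the Spearman correlation between each gene's spatial expression
#' profile and the activation map over the shared spatial units, and returns
#' the genes ranked by descending correlation (ties broken lexicographically
#' by gene id, so tables are byte-for-byte reproducible). Genes with a
#' constant profile have no defined rank correlation; they are recorded with
#' a missing `rho` and excluded from the ranking (a message reports the
#' count).
#'
#' @param expr genes x units numeric matrix; colnames are unit ids.
#' @param activation a [spatial_profile()] whose `unit_id`s match `expr`
#'   columns (same set; order taken from the profile).
#' @return data frame of class `correlation_table` with columns `gene_id`,
#'   `rho`, `p_spatial` (NA until filled by surrogate testing), `rank`;
#'   attributes `compartment`, `granularity`, `n_units`.
#' @export
correlate_genes <- function(expr, activation) {
  stopifnot(is.matrix(expr), inherits(activation, "spatial_profile"))
  units <- activation$unit_id
  if (!all(units %in% colnames(expr)))
    stop_imtx("unit-id mismatch: %d activation unit(s) absent from the expression matrix",
              sum(!units %in% colnames(expr)))
  n <- length(units)
  if (n <= 2) stop_imtx("need more than 2 spatial units")
  E <- expr[, units, drop = FALSE]
  const <- apply(E, 1, function(v) max(v) == min(v))
  if (any(const))
    message(sprintf("excluded %d constant-profile gene(s) from ranking",
                    sum(const)))
  R <- t(apply(E[!const, , drop = FALSE], 1, rank))
  zr <- standardize_ranks(rank(activation$value))
  Z <- t(apply(R, 1, standardize_ranks))
  rho <- as.numeric(Z %*% zr) / (n - 1)
  ord <- order(-rho, rownames(Z))
  tab <- data.frame(gene_id = rownames(Z)[ord],
                    rho = rho[ord],
                    p_spatial = NA_real_,
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (any(const)) {
    tab <- rbind(tab, data.frame(gene_id = rownames(E)[const],
                                 rho = NA_real_, p_spatial = NA_real_,
                                 rank = NA_integer_))
  }
  rownames(tab) <- NULL
  structure(tab,
            compartment = unique(activation$compartment),
            granularity = attr(activation, "granularity"),
            n_units = n,
            class = c("correlation_table", "data.frame"))
}

standardize_ranks <- function(r) {
  (r - mean(r)) / sd(r)
}

#' Threshold a correlation table into large-effect gene sets
#'
#' Splits a ranked table into the positively associated set
#' (`rho > rho_min`, strictly) and the negatively associated set
#' (`rho < -rho_min`), the large-effect-size convention used before
#' master-regulator analysis.
#'
#' @param table a [correlate_genes()] result.
#' @param rho_min threshold in (0, 1); default 0.5 (large effect size).
#' @return list with character vectors `positive` and `negative` (disjoint).
#' @export
threshold_correlations <- function(table, rho_min = 0.5) {
  stopifnot(inherits(table, "correlation_table"))
  if (!is.numeric(rho_min) || rho_min <= 0 || rho_min >= 1)
    stop_imtx("rho_min must lie strictly between 0 and 1")
  ok <- !is.na(table$rho)
  pos <- table$gene_id[ok & table$rho > rho_min]
  neg <- table$gene_id[ok & table$rho < -rho_min]
  if (length(pos) == 0 && length(neg) == 0)
    message("no correlations exceed the threshold in either direction")
  list(positive = pos, negative = neg)
}

#' Write a correlation table as TSV
#'
#' Columns: gene_id, compartment, granularity, rho, p_spatial, rank.
#'
#' @param table a `correlation_table`.
#' @param path output path.
#' @param header optional comment line (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "correlation_table"))
  out <- data.frame(gene_id = table$gene_id,
                    compartment = attr(table, "compartment"),
                    granularity = attr(table, "granularity"),
                    rho = table$rho,
                    p_spatial = table$p_spatial,
                    rank = table$rank)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
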