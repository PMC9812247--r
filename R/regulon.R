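#' Recovery AUC of a gene set under a motif ranking
#'
#' Area under the recovery curve within the top `ceil(auc_max_fraction * N)`
#' positions of a motif's genome-wide ranking:
#' `auc = sum_{x=1..R} y(x) / (|set| * R)` where `y(x)` counts set genes
#' ranked at or above `x`. A set entirely outside the window scores 0; a
#' single set gene at rank 1 scores 1.
#'
#' @param ranking integer ranks named by gene id (a complete tie-free
#'   permutation, 1 = top).
#' @param gene_set nonempty character vector of gene ids.
#' @param auc_max_fraction fraction of the ranking forming the AUC window,
#'   in (0, 0.2].
#' @return AUC in \[0, 1\].
#' @export
recovery_auc <- function(ranking, gene_set, auc_max_fraction = 0.05) {
  if (length(gene_set) == 0) stop_imtx("gene set must be nonempty")
  if (auc_max_fraction <= 0 || auc_max_fraction > 0.2)
    stop_imtx("auc_max_fraction must lie in (0, 0.2]")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% names(ranking)))
    stop_imtx("gene set contains ids absent from the ranking")
  N <- length(ranking)
  R <- ceiling(auc_max_fraction * N)
  r <- ranking[gene_set]
  sum(pmax(R - r + 1, 0)) / (length(gene_set) * R)
}

#' Normalized enrichment scores across a motif database
#'
#' Z-scores each motif's recovery AUC against the mean and sample standard
#' deviation over all motifs in the database.
#'
#' @param aucs named numeric vector of per-motif AUCs (>= 3 motifs).
#' @return named numeric vector of NES values.
#' @export
#' @examples
#' nes_scores(c(a = 0.1, b = 0.2, c = 0.3))  # -1, 0, 1
nes_scores <- function(aucs) {
  if (length(aucs) < 3) stop_imtx("need at least 3 motifs")
  s <- sd(aucs)
  if (s == 0) stop_imtx("degenerate database: all AUCs identical")
  (aucs - mean(aucs)) / s
}

#' Nominate master regulators from correlated gene sets
#'
#' For each direction (positive and negative large-effect sets from
#' [threshold_correlations()]): computes every motif's recovery AUC of the
#' input set, converts AUCs to NES, retains motifs with `nes > nes_min`
#' (strict), defines their targets as the input-set genes ranked inside the
#' AUC window, collapses multiple motifs per regulator to the motif with the
#' maximal NES, and finally reports the retained regulators that are members
#' of the risk-gene list, with the `"n_targets/n_possible"` convention
#' (targets recovered / input-set size). An empty input set yields an empty
#' cell (reported as `"-"` in the grid) with a warning.
#'
#' @param corr_table a [correlate_genes()] result.
#' @param db a `regulon_db` (list with `motifs` data frame and a
#'   motifs x genes rank matrix `ranks`).
#' @param risk_genes character vector of risk-gene ids.
#' @param rho_min correlation threshold (default 0.5, large effect size).
#' @param nes_min NES retention threshold (default 3, strict).
#' @param auc_max_fraction AUC window fraction (default 0.05).
#' @return object of class `regulon_report`: list with `nes_table` (all
#'   motifs x directions), `report` (risk-filtered regulators with targets),
#'   and `grid` (named character vector, one `"REG (n/N)"` or `"-"` cell per
#'   direction).
#' @export
master_regulators <- function(corr_table, db, risk_genes, rho_min = 0.5,
                              nes_min = 3, auc_max_fraction = 0.05) {
  stopifnot(inherits(corr_table, "correlation_table"),
            inherits(db, "regulon_db"))
  if (nrow(db$motifs) == 0) stop_imtx("empty regulon database")
  sets <- threshold_correlations(corr_table, rho_min)
  N <- ncol(db$ranks)
  R <- ceiling(auc_max_fraction * N)

  nes_rows <- list()
  report_rows <- list()
  grid <- c(positive = "-", negative = "-")
  for (direction in c("positive", "negative")) {
    set <- sets[[direction]]
    if (length(set) == 0) {
      warning(sprintf("empty %s gene set at rho_min = %g", direction,
                      rho_min), call. = FALSE)
      next
    }
    sub <- db$ranks[, set, drop = FALSE]
    aucs <- rowSums(pmax(R - sub + 1, 0)) / (length(set) * R)
    names(aucs) <- db$motifs$motif_id
    nes <- nes_scores(aucs)
    nes_rows[[direction]] <- data.frame(
      direction = direction,
      motif_id = db$motifs$motif_id,
      regulator_gene = db$motifs$regulator_gene,
      auc = unname(aucs), nes = unname(nes),
      stringsAsFactors = FALSE)

    retained <- which(nes > nes_min)
    if (length(retained) == 0) next
    rec <- lapply(retained, function(m) {
      targets <- set[sub[m, set] <= R]
      data.frame(direction = direction,
                 motif_id = db$motifs$motif_id[m],
                 regulator_gene = db$motifs$regulator_gene[m],
                 auc = unname(aucs[m]), nes = unname(nes[m]),
                 n_targets = length(targets),
                 n_possible = length(set),
                 targets = paste(sort(targets), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rec)
    # one motif per regulator: keep the motif with maximal NES
    rec <- rec[order(-rec$nes), ]
    rec <- rec[!duplicated(rec$regulator_gene), ]
    rec <- rec[rec$regulator_gene %in% risk_genes, , drop = FALSE]
    if (nrow(rec) > 0) {
      report_rows[[direction]] <- rec
      grid[direction] <- paste(sprintf("%s (%d/%d)", rec$regulator_gene,
                                       rec$n_targets, rec$n_possible),
                               collapse = "; ")
    }
  }
  nes_table <- if (length(nes_rows)) do.call(rbind, nes_rows)
               else data.frame()
  report <- if (length(report_rows)) do.call(rbind, report_rows)
            else data.frame()
  rownames(nes_table) <- rownames(report) <- NULL
  structure(list(nes_table = nes_table, report = report, grid = grid),
            class = "regulon_report")
}
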