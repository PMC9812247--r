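#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the study's conventional
#' defaults: 1000 surrogate maps, 20 cortical / 5 subcortical smoothing
#' neighbours, the large-effect correlation threshold 0.5, NES retention
#' threshold 3, GSEA weight 1, and the 5-200 category-size window. Only the
#' cortex and subcortex compartments are supported; the cerebellum is out of
#' scope (marginal activation in the task paradigms this models).
#'
#' @param synthetic a [synthetic_config()] describing the generated inputs.
#' @param compartments subset of `c("cortex", "subcortex")`.
#' @param paradigms number of synthetic activation maps (1 or 2; two are
#'   planted on disjoint gene sets).
#' @param granularity `"region"` (primary) and/or `"voxel"`.
#' @param n_surrogates per-gene surrogate ensemble size.
#' @param k_cortex,k_subcortex surrogate smoothing neighbours per
#'   compartment.
#' @param rho_min large-effect correlation threshold.
#' @param nes_min NES retention threshold.
#' @param gsea_weight GSEA weight exponent.
#' @param category_size inclusive category-size window.
#' @param n_perm_gsea GSEA permutations.
#' @param n_nulls_gcea GCEA ensemble size.
#' @param compute_gene_p if `TRUE`, per-gene surrogate p-values are computed
#'   (the pipeline's most expensive stage).
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   writing.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            compartments = c("cortex", "subcortex"),
                            paradigms = 2L,
                            granularity = "region",
                            n_surrogates = 1000,
                            k_cortex = 20, k_subcortex = 5,
                            rho_min = 0.5, nes_min = 3,
                            gsea_weight = 1,
                            category_size = c(5, 200),
                            n_perm_gsea = 1000,
                            n_nulls_gcea = 1000,
                            compute_gene_p = FALSE,
                            seed = 1L,
                            out_dir = NULL) {
  bad <- setdiff(compartments, c("cortex", "subcortex"))
  if (length(bad) > 0)
    stop_imtx("unsupported compartment(s): %s (only cortex and subcortex are analyzed)",
              paste(bad, collapse = ", "))
  if (length(compartments) == 0) stop_imtx("no compartment requested")
  if (!all(granularity %in% c("region", "voxel")))
    stop_imtx("granularity must be 'region' and/or 'voxel'")
  stopifnot(inherits(synthetic, "synthetic_config"),
            paradigms %in% c(1L, 2L))
  structure(list(synthetic = synthetic, compartments = compartments,
                 paradigms = as.integer(paradigms),
                 granularity = granularity,
                 n_surrogates = as.integer(n_surrogates),
                 k_cortex = as.integer(k_cortex),
                 k_subcortex = as.integer(k_subcortex),
                 rho_min = rho_min, nes_min = nes_min,
                 gsea_weight = gsea_weight,
                 category_size = category_size,
                 n_perm_gsea = as.integer(n_perm_gsea),
                 n_nulls_gcea = as.integer(n_nulls_gcea),
                 compute_gene_p = isTRUE(compute_gene_p),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  plain <- strip(config)
  plain$out_dir <- NULL   # provenance hashes the analysis, not the paths
  fnv1a_hash(as.character(
    jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null")))
}

#' Run the full imaging-transcriptomics pipeline on synthetic data
#'
#' Executes the stages in order: generate inputs, extract per-compartment
#' profiles, correlate genes with each activation map, (optionally) attach
#' per-gene surrogate p-values, compare paradigms by RRHO, run category
#' enrichment (positive and negative gene programs), risk-gene-set GSEA, and
#' master-regulator nomination. Identical `(config, seed)` produce
#' byte-identical outputs; every written TSV carries a header line with the
#' configuration hash and seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `result_bundle`: nested list with per
#'   (paradigm, compartment) correlation tables, enrichment, GSEA, regulon
#'   reports, per paradigm-pair RRHO results, the generated dataset, and
#'   provenance (`config_hash`, `seed`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  header <- sprintf("imtx config=%s seed=%d", hash, config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(writer, obj, name, ...) {
    if (is.null(out_dir)) return(invisible(NULL))
    writer(obj, file.path(out_dir, name), ...)
  }

  ds <- generate_dataset(config$synthetic, paradigms = config$paradigms)
  bundle <- list(correlations = list(), enrichment = list(), gsea = list(),
                 regulons = list(), rrho = list(), dataset = ds,
                 provenance = list(config_hash = hash, seed = config$seed))

  for (par in names(ds$activations)) {
    act_all <- ds$activations[[par]]
    for (comp in config$compartments) {
      act <- subset_compartment(act_all, comp)
      k <- if (comp == "cortex") config$k_cortex else config$k_subcortex
      k <- min(k, nrow(act) - 1L)
      tab <- correlate_genes(ds$expression, act)
      if (config$compute_gene_p) {
        tab <- surrogate_pvalues(tab, ds$expression, act,
                                 k_neighbors = k,
                                 n_surrogates = config$n_surrogates,
                                 seed = substream_seed(config$seed,
                                                       paste(par, comp)))
      }
      key <- paste(par, comp, sep = ".")
      bundle$correlations[[key]] <- tab
      emit(write_correlation_tsv, tab,
           sprintf("correlations_%s_%s_region.tsv", par, comp),
           header = header)

      for (direction in c("positive", "negative")) {
        sc <- gene_scores(tab, direction)
        enr <- gcea(sc, ds$annotations, act, ds$expression,
                    n_nulls = config$n_nulls_gcea,
                    seed = substream_seed(config$seed,
                                          paste("gcea", par, comp, direction)),
                    k_neighbors = k,
                    size_range = config$category_size)
        bundle$enrichment[[paste(key, direction, sep = ".")]] <- enr
        emit(write_enrichment_tsv, enr,
             sprintf("enrichment_%s_%s_%s.tsv", par, comp, direction),
             header = header)
      }

      gs <- gsea_pvalue(tab, intersect(ds$risk_genes, tab$gene_id),
                        weight_exponent = config$gsea_weight,
                        n_perm = config$n_perm_gsea,
                        seed = substream_seed(config$seed,
                                              paste("gsea", par, comp)))
      bundle$gsea[[key]] <- gs

      reg <- suppressWarnings(
        master_regulators(tab, ds$regulon_db, ds$risk_genes,
                          rho_min = config$rho_min,
                          nes_min = config$nes_min))
      bundle$regulons[[key]] <- reg
      emit(write_regulon_tsv, reg,
           sprintf("regulons_%s_%s.tsv", par, comp), header = header)
    }
  }

  pars <- names(ds$activations)
  if (length(pars) == 2) {
    for (comp in config$compartments) {
      k1 <- paste(pars[1], comp, sep = ".")
      k2 <- paste(pars[2], comp, sep = ".")
      rr <- rrho_map(bundle$correlations[[k1]], bundle$correlations[[k2]],
                     seed = substream_seed(config$seed, paste("rrho", comp)))
      bundle$rrho[[comp]] <- rr
      emit(write_rrho_tsv, rr, sprintf("rrho_%s_vs_%s_%s.tsv", pars[1],
                                       pars[2], comp), header = header)
    }
  }

  if (!is.null(out_dir)) {
    manifest <- list(config_hash = hash, seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("imtx")),
                     files = sort(list.files(out_dir)))
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(bundle) <- "result_bundle"
  bundle
}

write_enrichment_tsv <- function(enr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(as.data.frame(enr), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

write_regulon_tsv <- function(reg, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# positive\t%s", reg$grid[["positive"]]), con)
  writeLines(sprintf("# negative\t%s", reg$grid[["negative"]]), con)
  if (NROW(reg$report) > 0)
    write.table(reg$report, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

write_rrho_tsv <- function(rr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# rho_rrho\t%.6f\tp_rrho\t%g\tstep\t%d",
                     rr$rho_rrho, rr$p_rrho, rr$step), con)
  write.table(rr$signed_logp, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarise a regulon grid across compartments
#'
#' Assembles the compartment x direction master-regulator grid (the
#' two-by-two summary used for reporting), with `"-"` for empty cells.
#'
#' @param bundle a [run_pipeline()] result.
#' @param paradigm paradigm name (e.g. `"paradigm1"`).
#' @return data frame with one row per compartment and columns
#'   `negative`, `positive`.
#' @export
regulon_grid <- function(bundle, paradigm = "paradigm1") {
  stopifnot(inherits(bundle, "result_bundle"))
  comps <- sub(paste0("^", paradigm, "\\."), "",
               grep(paste0("^", paradigm, "\\."), names(bundle$regulons),
                    value = TRUE))
  rows <- lapply(comps, function(comp) {
    g <- bundle$regulons[[paste(paradigm, comp, sep = ".")]]$grid
    data.frame(compartment = comp, negative = g[["negative"]],
               positive = g[["positive"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
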