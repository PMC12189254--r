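# End-to-end orchestration: per-dose differential expression, dose-
# consistency filtering, over-representation analysis and hierarchical
# pathway perturbation profiling, with plain-file stage outputs and a JSON
# run manifest. Every stage writes an ordinary TSV so any one of them can be
# swapped for an external tool's output for cross-validation.

#' Bin significant genes by fold-change magnitude
#'
#' Standard perturbation-intensity bins on |log2FC|: minimal \[0, 0.25),
#' low \[0.25, 1), moderate \[1, 2) and high >= 2. A fold change of exactly
#' 2 falls in the high bin. Counts sum to the number of input genes.
#'
#' @param lfc log2 fold changes of significant genes.
#' @return named integer vector (minimal, low, moderate, high).
#' @export
bin_degs_by_lfc <- function(lfc) {
  lfc <- abs(lfc[!is.na(lfc)])
  c(minimal = sum(lfc < 0.25),
    low = sum(lfc >= 0.25 & lfc < 1),
    moderate = sum(lfc >= 1 & lfc < 2),
    high = sum(lfc >= 2))
}

#' Run the full multi-dose analysis chain
#'
#' simulate/load -> per-dose DE -> dose-consistency filter -> ORA ->
#' hierarchical perturbation analysis, writing one TSV per stage plus a JSON
#' manifest into `out_dir`. Any stage failure aborts with the failing stage
#' named.
#'
#' @param counts count matrix.
#' @param design design table.
#' @param collection `gene_set_collection`.
#' @param hierarchy validated parent-child table.
#' @param topologies named list of `pathway_topology`.
#' @param roots hierarchy roots to traverse in the perturbation stage.
#' @param out_dir output directory (created if needed).
#' @param alpha per-dose DEG significance level.
#' @param tau,r2_min filter parameters.
#' @param universe ORA universe: character vector or size; defaults to the
#'   measured genes.
#' @param ora_threshold FDR threshold for the stringent ORA flag.
#' @param n_boot bootstrap replicates for the perturbation stage.
#' @param seed global seed.
#' @return (invisibly) list with all in-memory stage results.
#' @export
run_all <- function(counts, design, collection, hierarchy, topologies,
                    roots, out_dir, alpha = 0.05, tau = 0.1, r2_min = 0.5,
                    universe = NULL, ora_threshold = 5e-8, n_boot = 2000,
                    seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(universe)) universe <- rownames(counts)

  de_list <- stage("dea", run_dea(counts, design, alpha = alpha))
  for (d in names(de_list))
    utils::write.table(de_list[[d]], file.path(out_dir, paste0("dea_", d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  series <- stage("filter", build_dose_series(de_list))
  filt <- stage("filter", filter_degs(series, tau = tau, r2_min = r2_min))
  writeLines(filt$retained, file.path(out_dir, "retained_genes.txt"))
  utils::write.table(filt$verdicts, file.path(out_dir, "filter_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ora <- stage("ora", run_ora(filt$retained, collection, universe = universe,
                              alpha_strict = ora_threshold))
  utils::write.table(ora, file.path(out_dir, "ora.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dose_inputs <- lapply(de_list, function(d) {
    de <- d$gene_id[d$significant]
    list(deltaE = stats::setNames(d$log2FC[d$significant], de), de_genes = de)
  })
  spia <- stage("spia", traverse_hierarchy(
    hierarchy, topologies, dose_inputs, roots,
    universe_genes = rownames(counts), n_boot = n_boot, seed = seed))
  utils::write.table(spia$results, file.path(out_dir, "spia_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(spia$profile, file.path(out_dir, "spia_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bins <- lapply(de_list, function(d) bin_degs_by_lfc(d$log2FC[d$significant]))
  bins_tab <- data.frame(dose = as.numeric(names(de_list)),
                         do.call(rbind, bins))
  utils::write.table(bins_tab, file.path(out_dir, "deg_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_manifest(
    file.path(out_dir, "manifest.json"),
    inputs = list(n_genes = nrow(counts), n_samples = ncol(counts),
                  n_sets = length(collection$sets)),
    params = list(alpha = alpha, tau = tau, r2_min = r2_min,
                  ora_threshold = ora_threshold, n_boot = n_boot,
                  universe = if (is.character(universe)) length(universe)
                             else universe),
    seed = seed,
    stage_counts = list(
      dea = vapply(de_list, function(d) sum(d$significant), 1L),
      retained = length(filt$retained),
      ora_significant = sum(ora$significant),
      spia_rows = nrow(spia$results)))

  invisible(list(dea = de_list, series = series, filter = filt, ora = ora,
                 spia = spia, bins = bins_tab))
}
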