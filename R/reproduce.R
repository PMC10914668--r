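# External reproduction: run the full analysis on a locally supplied
# deposited-format data directory and report the headline quantities.

#' Reproduce the headline analysis from a deposited data directory
#'
#' Runs the complete pipeline on real input files (a Ki record export plus
#' agonism, clinical and grouping tables) and returns the headline
#' quantities of the analysis: the human-record count, the retained
#' drug/receptor counts, the minimum retained pKi, the number of derived
#' clusters, the variance shares of the leading components, and the
#' per-scheme median errors and permutation p-values. The required data are
#' an external download and are not bundled with the package; the expected
#' directory layout is `ki_records.tsv` (columns drug, receptor, species,
#' ki_nM, source_id), `agonism.tsv`, `clinical.tsv`, and any number of
#' `grouping_<name>.tsv` files, i.e. the dialect written by
#' [write_synthetic()].
#'
#' @param dir directory containing the data files.
#' @param n_perm permutation replicates for the predictive-validity tests.
#' @param seed master seed.
#' @param q_ppca imputation PPCA rank.
#' @return list with `n_human_records`, `n_drugs`, `n_receptors`,
#'   `min_pki`, `n_clusters`, `variance_explained_top3`,
#'   `variance_explained_component4`, `ranking`, and the full pipeline
#'   `result`.
#' @export
reproduce_reported_analysis <- function(dir, n_perm = 500L, seed = 1L,
                                        q_ppca = 5L) {
  f <- function(x) file.path(dir, x)
  if (!file.exists(f("ki_records.tsv")))
    stop("reproduce_reported_analysis: ", f("ki_records.tsv"), " not found")
  groupings <- list.files(dir, pattern = "^grouping_.*\\.tsv$",
                          full.names = TRUE)
  names(groupings) <- sub("^grouping_(.*)\\.tsv$", "\\1", basename(groupings))
  cfg <- run_config(
    inputs = list(ki_records = f("ki_records.tsv"),
                  agonism = if (file.exists(f("agonism.tsv")))
                    f("agonism.tsv") else NULL,
                  clinical = if (file.exists(f("clinical.tsv")))
                    f("clinical.tsv") else NULL,
                  groupings = as.list(groupings)),
    q_ppca = q_ppca, n_perm = n_perm, seed = seed)
  human <- filter_human(parse_ki_table(f("ki_records.tsv")))
  res <- run_all(cfg)
  ve_all <- attr(res$variance_explained, "all")
  list(n_human_records = nrow(human),
       n_drugs = nrow(res$affinity$values),
       n_receptors = ncol(res$affinity$values),
       min_pki = min(res$affinity$values, na.rm = TRUE),
       n_clusters = res$partition$n_clusters,
       variance_explained_top3 = sum(ve_all[1:3]),
       variance_explained_component4 = ve_all[4],
       ranking = res$ranking,
       result = res)
}
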