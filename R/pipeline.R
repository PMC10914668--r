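# Pipeline: end-to-end orchestration (ingest -> preprocess -> impute ->
# cluster -> characterize -> predict) from one configuration, with
# deterministic seeds and plain-text artifact output.

#' Build a run configuration
#'
#' Exactly one of `inputs` (paths to real data files) or `synthetic` (a
#' [synthetic_config()]) must be supplied. All randomness derives from the
#' single `seed`, expanded deterministically into per-stage seeds; no stage
#' reads the wall clock.
#'
#' @param inputs named list of paths: `ki_records`, and optionally
#'   `agonism`, `clinical`, plus a named list `groupings` of
#'   scheme-name -> path.
#' @param synthetic a `synthetic_config`.
#' @param min_drugs_per_receptor,min_receptors_per_drug ingest filters.
#' @param floor pKi floor constant.
#' @param q_ppca rank of the imputation PPCA.
#' @param negative_policy edge-weight policy, see [build_graph()].
#' @param n_restarts Louvain restarts.
#' @param n_components,q_impute,n_perm prediction-stage parameters.
#' @param include_receptor_profile also score the full fingerprint matrix
#'   as a predictor set.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs = NULL, synthetic = NULL,
                       min_drugs_per_receptor = 5L,
                       min_receptors_per_drug = 5L, floor = 4,
                       q_ppca = 5L, negative_policy = "clip_zero",
                       n_restarts = 100L, n_components = 2L,
                       q_impute = 2L, n_perm = 500L,
                       include_receptor_profile = TRUE, seed = 1L) {
  if (is.null(inputs) == is.null(synthetic))
    stop("run_config: supply exactly one of 'inputs' or 'synthetic'")
  structure(list(inputs = inputs, synthetic = synthetic,
                 min_drugs_per_receptor = min_drugs_per_receptor,
                 min_receptors_per_drug = min_receptors_per_drug,
                 floor = floor, q_ppca = q_ppca,
                 negative_policy = negative_policy,
                 n_restarts = n_restarts, n_components = n_components,
                 q_impute = q_impute, n_perm = n_perm,
                 include_receptor_profile = include_receptor_profile,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML with optional `inputs:` and `synthetic:` sections
#' mirroring the arguments of [run_config()] and [synthetic_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_config, y$synthetic)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Ingests (or generates) the data, assembles and adjusts the affinity
#' matrix, fits the imputation PPCA, builds the correlation graph, derives
#' the Louvain partition, characterizes the clusters, and scores every
#' configured predictor scheme by LOO-PLS permutation testing. When
#' `outdir` is given, every artifact is written as delimited/structured
#' text together with a manifest of all parameters and seeds.
#'
#' @param config a `run_config`.
#' @param outdir optional output directory.
#' @return (invisibly when writing) a list with all intermediate and final
#'   objects: `affinity`, `adjusted`, `ppca`, `completed`, `similarity`,
#'   `graph`, `partition`, `scores`, `variance_explained`,
#'   `characterization`, `reports`, `ranking`, `manifest`.
#' @export
run_all <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, c("ppca", "louvain", "predict"))
  warnings_log <- character(0)
  wh <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
                      invokeRestart("muffleWarning") }

  if (!is.null(config$synthetic)) {
    dat <- generate_synthetic(config$synthetic)
    records <- dat$records
    agonism <- dat$agonism
    clinical <- dat$clinical
    schemes <- dat$groupings
  } else {
    paths <- config$inputs
    need <- paths$ki_records
    if (is.null(need) || !file.exists(need))
      stop("run_all: Ki record file not found: ",
           if (is.null(need)) "<unset>" else need)
    for (nm in c("agonism", "clinical")) {
      pth <- paths[[nm]]
      if (!is.null(pth) && !file.exists(pth))
        stop("run_all: ", nm, " file not found: ", pth)
    }
    records <- parse_ki_table(paths$ki_records)
    agonism <- if (!is.null(paths$agonism)) parse_agonism(paths$agonism) else NULL
    clinical <- if (!is.null(paths$clinical)) parse_clinical_table(paths$clinical) else NULL
    schemes <- list()
    for (nm in names(paths$groupings)) {
      if (!file.exists(paths$groupings[[nm]]))
        stop("run_all: grouping file not found: ", paths$groupings[[nm]])
      schemes[[nm]] <- parse_grouping(paths$groupings[[nm]], nm)
    }
    dat <- NULL
  }

  am <- withCallingHandlers(
    build_affinity_matrix(filter_human(records),
                          config$min_drugs_per_receptor,
                          config$min_receptors_per_drug),
    warning = wh)
  adj <- withCallingHandlers(
    adjust_affinities(am, agonism, floor = config$floor), warning = wh)
  fit <- fit_ppca(adj, q = config$q_ppca, seed = seeds["ppca"])
  completed <- ppca_impute(fit, adj)
  sim <- correlation_matrix(completed)
  graph <- build_graph(sim, config$negative_policy)
  part <- louvain_partition(graph, seed = seeds["louvain"],
                            n_restarts = config$n_restarts)
  sc <- ppca_scores(fit, completed)
  ve <- variance_explained(fit, completed)

  characterization <- list(
    cluster_mean_scores = cluster_mean_scores(sc, part,
                                              k = min(3L, fit$q)),
    receptor_loadings = component_receptor_loadings(fit,
                                                    k = min(3L, fit$q)))
  if (!is.null(clinical)) {
    characterization$component_effect_correlation <-
      withCallingHandlers(
        correlate_components_with_effects(sc, clinical), warning = wh)
    characterization$cluster_mean_effects <-
      cluster_mean_effects(clinical, part)
  }

  reports <- list()
  if (!is.null(clinical)) {
    preds <- list(derived_clusters = encode_predictors(
      partition_to_scheme(part)))
    for (nm in names(schemes))
      preds[[nm]] <- encode_predictors(schemes[[nm]])
    if (isTRUE(config$include_receptor_profile))
      preds$receptor_profile <- encode_predictors(completed)
    pseeds <- derive_seeds(seeds["predict"], names(preds))
    for (nm in names(preds)) {
      reports[[nm]] <- withCallingHandlers(
        permutation_test(preds[[nm]], clinical, n_perm = config$n_perm,
                         n_components = config$n_components,
                         q_impute = config$q_impute, seed = pseeds[nm]),
        warning = wh)
    }
  }
  ranking <- if (length(reports) >= 2L) compare_schemes(reports) else NULL

  manifest <- list(parameters = unclass(config[setdiff(names(config),
                                                       c("inputs", "synthetic"))]),
                   synthetic = if (!is.null(config$synthetic))
                     unclass(config$synthetic) else NULL,
                   inputs = config$inputs,
                   stage_seeds = as.list(seeds),
                   n_drugs = nrow(am$values), n_receptors = ncol(am$values),
                   n_clusters = part$n_clusters,
                   modularity = part$modularity,
                   negative_policy = config$negative_policy,
                   schemes = names(reports),
                   warnings = unique(warnings_log),
                   package_version = as.character(utils::packageVersion("apclust")))

  result <- list(data = dat, affinity = am, adjusted = adj, ppca = fit,
                 completed = completed, similarity = sim, graph = graph,
                 partition = part, scores = sc, variance_explained = ve,
                 characterization = characterization, reports = reports,
                 ranking = ranking, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_affinity_tsv(am, file.path(outdir, "affinity_matrix.tsv"))
    write_affinity_tsv(adj, file.path(outdir, "adjusted_matrix.tsv"))
    write_matrix_tsv(completed$values, file.path(outdir, "completed_matrix.tsv"))
    write_matrix_tsv(sim$values, file.path(outdir, "similarity_matrix.tsv"))
    write.table(data.frame(drug = names(part$assignment),
                           cluster_id = part$assignment),
                file.path(outdir, "partition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix_tsv(sc, file.path(outdir, "component_scores.tsv"))
    write_matrix_tsv(characterization$cluster_mean_scores,
                     file.path(outdir, "cluster_mean_scores.tsv"),
                     key = "cluster")
    write_matrix_tsv(characterization$receptor_loadings,
                     file.path(outdir, "receptor_loadings.tsv"),
                     key = "receptor")
    if (!is.null(clinical)) {
      write_matrix_tsv(characterization$component_effect_correlation$r,
                       file.path(outdir, "component_effect_correlation.tsv"),
                       key = "component")
      write_matrix_tsv(characterization$cluster_mean_effects$mean,
                       file.path(outdir, "cluster_mean_effects.tsv"),
                       key = "cluster")
    }
    for (nm in names(reports)) {
      rp <- reports[[nm]]
      jsonlite::write_json(
        list(scheme = rp$scheme, D = rp$D,
             observed_median_error = rp$observed_median_error,
             p_value = rp$p_value, n_perm = rp$n_perm, seed = rp$seed),
        file.path(outdir, paste0("report_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
      write.table(data.frame(null_median_error = rp$null_median_errors),
                  file.path(outdir, paste0("null_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(ranking))
      write.table(ranking, file.path(outdir, "scheme_ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(result))
  }
  result
}

#' Rank categorization schemes by out-of-sample error
#'
#' @param reports list of `prediction_report`s computed on the same
#'   clinical table.
#' @return data frame with `scheme`, `D`, `observed_median_error`,
#'   `p_value`, sorted by error ascending (ties by scheme name).
#' @export
compare_schemes <- function(reports) {
  if (length(reports) < 2L) stop("compare_schemes: need at least 2 reports")
  drug_sets <- lapply(reports, function(r) sort(names(r$per_drug_errors)))
  if (!all(vapply(drug_sets, identical, logical(1), drug_sets[[1]])))
    stop("compare_schemes: reports cover different drug sets")
  df <- data.frame(
    scheme = vapply(reports, `[[`, character(1), "scheme"),
    D = vapply(reports, `[[`, numeric(1), "D"),
    observed_median_error = vapply(reports, `[[`, numeric(1),
                                   "observed_median_error"),
    p_value = vapply(reports, function(r)
      if (is.null(r$p_value)) NA_real_ else r$p_value, numeric(1)),
    row.names = NULL)
  df[order(df$observed_median_error, df$scheme), , drop = FALSE]
}
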