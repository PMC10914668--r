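# Synthetic data: planted-cluster affinity fingerprints, replicate Ki
# records, agonism flags, group-linked clinical effects and grouping
# schemes, with the ground truth returned alongside.

#' Configuration for the synthetic-data generator
#'
#' Cluster centers sit at a constant weak-binding baseline plus a bump of
#' height `separation * noise_sd` on each cluster's own disjoint block of
#' signature receptors, so `separation` is the standardized per-receptor
#' contrast between a cluster and the rest at its signature sites (0 = no
#' cluster signal). Agonism is planted per cluster: with probability
#' `agonist_fraction` a cluster's signature bump is negated (the cluster
#' acts as an agonist at its own receptors, as dopamine partial agonists do
#' at D2), which leaves the between-cluster geometry unchanged because the
#' blocks are disjoint.
#'
#' @param n_drugs,n_receptors,n_clusters dimensions of the planted design.
#' @param separation standardized contrast (in units of `noise_sd`) between
#'   a cluster's center and the shared baseline at each of its signature
#'   receptors (0 = no cluster signal).
#' @param noise_sd within-cluster standard deviation per receptor, in
#'   floored-pKi units.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`; masks are
#'   rejection-sampled until every drug has `min_row_obs` and every
#'   receptor `min_col_obs` observed cells.
#' @param agonist_fraction probability that a cluster's signature bump is
#'   planted with a negative (agonist) sign.
#' @param effect_link `"group"` (effects are a noisy function of cluster
#'   membership) or `"profile"` (a noisy linear map of the fingerprint).
#' @param effect_noise_sd residual sd of the clinical effects.
#' @param group_effect_sd sd of the per-cluster true effect coefficients
#'   (between-group signal scale).
#' @param n_effects number of clinical effect columns (16 gives the
#'   canonical 13 side effects + 3 efficacy columns).
#' @param effect_missing_rate MCAR missingness of clinical scores.
#' @param records_per_cell replicate Ki measurements per observed cell
#'   (replicates are scattered log-normally around the cell's true Ki so
#'   that median aggregation is exercised on the Ki scale; a single record
#'   is emitted exactly).
#' @param rat_record_rate fraction of cells that additionally emit a
#'   rat-tissue distractor record (exercises the human-tissue filter).
#' @param min_row_obs,min_col_obs per-row/column minimum observed cells
#'   enforced by rejection sampling of the mask.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 27L, n_receptors = 42L,
                             n_clusters = 4L, separation = 8,
                             noise_sd = 0.5, missing_rate = 0.2,
                             agonist_fraction = 0.25,
                             effect_link = c("group", "profile"),
                             effect_noise_sd = 0.4, group_effect_sd = 1,
                             n_effects = 16L, effect_missing_rate = 0,
                             records_per_cell = 3L, rat_record_rate = 0.1,
                             min_row_obs = 1L, min_col_obs = 1L,
                             seed = 1L) {
  effect_link <- match.arg(effect_link)
  stopifnot(n_clusters <= n_drugs, n_clusters >= 1, separation >= 0,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            agonist_fraction >= 0, agonist_fraction <= 1,
            records_per_cell >= 1, effect_noise_sd >= 0,
            effect_missing_rate >= 0, effect_missing_rate < 1)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_receptors = as.integer(n_receptors),
                 n_clusters = as.integer(n_clusters),
                 separation = separation, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 agonist_fraction = agonist_fraction,
                 effect_link = effect_link,
                 effect_noise_sd = effect_noise_sd,
                 group_effect_sd = group_effect_sd,
                 n_effects = as.integer(n_effects),
                 effect_missing_rate = effect_missing_rate,
                 records_per_cell = as.integer(records_per_cell),
                 rat_record_rate = rat_record_rate,
                 min_row_obs = as.integer(min_row_obs),
                 min_col_obs = as.integer(min_col_obs),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sample_mcar_mask <- function(n, p, rate, min_row, min_col, max_tries = 1000L) {
  if (rate == 0) return(matrix(TRUE, n, p))
  for (t in seq_len(max_tries)) {
    keep <- matrix(rbinom(n * p, 1L, 1 - rate) == 1L, n, p)
    if (all(rowSums(keep) >= min_row) && all(colSums(keep) >= min_col))
      return(keep)
  }
  stop("sample_mcar_mask: could not satisfy the per-row/column observation ",
       "minima at missing_rate = ", rate, " after ", max_tries, " tries")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Emits the same four inputs the real pipeline consumes — Ki records (with
#' replicate measurements and rat-tissue distractors), an agonism table, a
#' clinical effect table and grouping schemes — plus the planted truth
#' (partition, cluster centers, effect coefficients, and the complete
#' pre-missingness adjusted and pKi matrices).
#'
#' @param config a `synthetic_config`.
#' @return list with elements `records` (`ki_records`), `agonism`
#'   (`agonism_table`), `clinical` (`clinical_profile`), `groupings` (list
#'   of `grouping_scheme`: the planted truth and a label-shuffled control),
#'   `truth`, and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_drugs; p <- config$n_receptors; K <- config$n_clusters
  drugs <- sprintf("drug%02d", seq_len(n))
  receptors <- sprintf("r%02d", seq_len(p))
  assign <- sort(rep_len(seq_len(K), n))
  names(assign) <- drugs

  # equidistant centers: constant baseline (contributes no across-receptor
  # variance, so correlations are driven by cluster structure) plus
  # per-cluster bumps of height separation * noise_sd on disjoint signature
  # receptor blocks (a standardized per-receptor contrast, so all pairwise
  # center relations are identical). A cluster's bump is negated with
  # probability agonist_fraction (the cluster acts as an agonist at its
  # signature receptors), which leaves the geometry unchanged because the
  # blocks are disjoint.
  block <- max(1L, min(5L, p %/% max(K, 1L)))
  delta <- if (config$noise_sd > 0) config$separation * config$noise_sd
           else config$separation
  baseline <- 1
  centers <- matrix(baseline, K, p, dimnames = list(NULL, receptors))
  bump_sign <- ifelse(runif(K) < config$agonist_fraction, -1, 1)
  for (k in seq_len(K))
    centers[k, ((k - 1L) * block + 1L):(k * block)] <-
      baseline + bump_sign[k] * delta

  F_adj <- centers[assign, , drop = FALSE] +
    matrix(rnorm(n * p, sd = config$noise_sd), n, p)
  dimnames(F_adj) <- list(drugs, receptors)
  complete_pki <- 4 + abs(F_adj)
  flags <- F_adj < 0

  keep <- sample_mcar_mask(n, p, config$missing_rate,
                           config$min_row_obs, config$min_col_obs)
  dimnames(keep) <- list(drugs, receptors)

  # Ki records for observed cells (replicates scattered log-normally)
  cells <- which(keep, arr.ind = TRUE)
  rpc <- config$records_per_cell
  rec <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    i <- cells[ci, 1]; j <- cells[ci, 2]
    ki_true <- 10^(9 - complete_pki[i, j])
    ki <- if (rpc == 1L) ki_true else ki_true * exp(rnorm(rpc, sd = 0.2))
    rec[[ci]] <- data.frame(
      drug = drugs[i], receptor = receptors[j], species = "human",
      ki_nM = ki, source_id = sprintf("synth_%s_%s_%d", drugs[i],
                                      receptors[j], seq_len(rpc)),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  if (config$rat_record_rate > 0) {
    rat_cells <- cells[runif(nrow(cells)) < config$rat_record_rate, ,
                       drop = FALSE]
    if (nrow(rat_cells) > 0) {
      rat <- data.frame(
        drug = drugs[rat_cells[, 1]], receptor = receptors[rat_cells[, 2]],
        species = "rat",
        ki_nM = 10^(9 - complete_pki[rat_cells]) *
          exp(rnorm(nrow(rat_cells), sd = 0.5)),
        source_id = sprintf("synth_rat_%d", seq_len(nrow(rat_cells))),
        stringsAsFactors = FALSE)
      records <- rbind(records, rat)
    }
  }
  records <- structure(records, class = c("ki_records", "data.frame"))

  flag_cells <- which(flags, arr.ind = TRUE)
  agonism <- if (nrow(flag_cells) > 0) {
    agonism_table(drugs[flag_cells[, 1]], receptors[flag_cells[, 2]],
                  sample(c("agonist", "partial_agonist"),
                         nrow(flag_cells), replace = TRUE))
  } else agonism_table()

  # clinical effects
  k_eff <- config$n_effects
  eff_names <- if (k_eff == 16L) names(clinical_effect_schema())
               else sprintf("effect%02d", seq_len(k_eff))
  if (config$effect_link == "group") {
    coefs <- matrix(rnorm(K * k_eff, sd = config$group_effect_sd), K, k_eff,
                    dimnames = list(paste0("cluster", seq_len(K)), eff_names))
    E <- coefs[assign, , drop = FALSE]
  } else {
    coefs <- matrix(rnorm(p * k_eff, sd = 1 / sqrt(p)), p, k_eff,
                    dimnames = list(receptors, eff_names))
    E <- F_adj %*% coefs
  }
  E <- E + matrix(rnorm(n * k_eff, sd = config$effect_noise_sd), n, k_eff)
  dimnames(E) <- list(drugs, eff_names)
  if (config$effect_missing_rate > 0) {
    em <- sample_mcar_mask(n, k_eff, config$effect_missing_rate, 1L, 1L)
    E[!em] <- NA_real_
  }
  kind <- if (k_eff == 16L) clinical_effect_schema() else
    stats::setNames(rep("side_effect", k_eff), eff_names)
  clinical <- new_clinical_profile(E, kind[eff_names])

  truth_scheme <- grouping_scheme(stats::setNames(paste0("cluster", assign),
                                                  drugs), "planted_clusters")
  shuffled <- grouping_scheme(stats::setNames(
    paste0("cluster", sample(assign)), drugs), "shuffled_clusters")

  values <- complete_pki
  values[!keep] <- NA_real_

  list(records = records, agonism = agonism, clinical = clinical,
       groupings = list(planted = truth_scheme, shuffled = shuffled),
       truth = list(partition = assign, centers = centers,
                    effect_coefficients = coefs,
                    complete_adjusted = F_adj,
                    complete_pki = complete_pki,
                    observed_mask = keep,
                    pki_with_missing = values),
       config = config)
}

#' Study-shaped synthetic fixture
#'
#' Convenience wrapper producing the canonical study-sized dataset: 27
#' drugs x 42 receptors, 4 planted clusters, 16 clinical effect columns,
#' separation 8, within-cluster noise sd 0.5, 20% affinity missingness,
#' 10% clinical missingness, 3 replicate records per cell. The
#' per-row/column observation minimum is 5 so the assembled matrix survives
#' the default inclusion filters intact.
#'
#' @param seed integer seed.
#' @return see [generate_synthetic()].
#' @export
study_shaped_fixture <- function(seed = 1L) {
  generate_synthetic(synthetic_config(
    n_drugs = 27L, n_receptors = 42L, n_clusters = 4L, separation = 8,
    noise_sd = 0.5, missing_rate = 0.2, agonist_fraction = 0.25,
    effect_link = "group", effect_noise_sd = 0.4, group_effect_sd = 1,
    n_effects = 16L, effect_missing_rate = 0.1, records_per_cell = 3L,
    min_row_obs = 5L, min_col_obs = 5L, seed = seed))
}

#' Write a synthetic dataset to the TSV dialects the ingest module reads
#'
#' @param dat output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; writes `ki_records.tsv`,
#'   `agonism.tsv`, `clinical.tsv`, `grouping_<name>.tsv` and
#'   `manifest.json` (config + seed).
#' @export
write_synthetic <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(dat$records, file.path(dir, "ki_records.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dat$agonism, file.path(dir, "agonism.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(dat$clinical$scores, file.path(dir, "clinical.tsv"))
  for (g in dat$groupings) {
    df <- data.frame(drug = names(g$assignment), category = g$assignment)
    write.table(df, file.path(dir, paste0("grouping_", g$name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(dat$config),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
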