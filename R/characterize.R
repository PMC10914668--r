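# Characterize: pharmacological and clinical summaries of the derived
# clusters (numeric equivalents of the cluster/component heatmaps).

align_drugs <- function(a, b, what = "tables") {
  common <- intersect(a, b)
  if (length(common) == 0L) stop("no shared drugs between ", what)
  common
}

#' Mean component scores per cluster
#'
#' For each cluster, the mean of its member drugs' scores on the top-k
#' latent components. (Clusters contain drugs, so cluster summaries use drug
#' scores; receptor-side summaries use the loading vectors, see
#' [component_receptor_loadings()].)
#'
#' @param scores n x q score matrix from [ppca_scores()].
#' @param partition a `partition` or `grouping_scheme` covering the drugs.
#' @param k number of leading components to summarize (default 3).
#' @return cluster x k matrix of mean scores.
#' @export
cluster_mean_scores <- function(scores, partition, k = 3L) {
  if (k > ncol(scores))
    stop("cluster_mean_scores: k exceeds the number of components")
  memb <- partition$assignment
  drugs <- align_drugs(rownames(scores), names(memb), "scores and partition")
  memb <- memb[drugs]
  S <- scores[drugs, seq_len(k), drop = FALSE]
  ids <- sort(unique(as.character(memb)))
  out <- t(vapply(ids, function(cid) {
    rows <- memb == cid
    if (!any(rows)) stop("cluster_mean_scores: empty cluster ", cid)
    colMeans(S[rows, , drop = FALSE])
  }, numeric(k)))
  dimnames(out) <- list(ids, colnames(scores)[seq_len(k)])
  out
}

#' Receptor loadings of the leading components
#'
#' The orthonormal principal axes of the fitted model restricted to the
#' top-k components, sign-fixed so the largest-magnitude loading in each
#' column is positive. Rows are receptors.
#'
#' @param model a fitted `ppca_model`.
#' @param k number of leading components (default 3).
#' @return receptor x k loading matrix.
#' @export
component_receptor_loadings <- function(model, k = 3L) {
  if (k > model$q)
    stop("component_receptor_loadings: k exceeds the model's q")
  L <- model$axes[, seq_len(k), drop = FALSE]
  colnames(L) <- paste0("component_", seq_len(k))
  L
}

#' Correlate component scores with clinical effects
#'
#' Pearson correlation, across drugs, between each leading component score
#' and each clinical effect, using pairwise-complete observations. Cells
#' with fewer than 3 complete pairs or zero variance are masked (`NA`) with
#' a warning.
#'
#' @param scores n x k component score matrix (drugs as rownames).
#' @param clinical a `clinical_profile`.
#' @param k number of leading components (default `min(3, ncol(scores))`).
#' @return list with `r` (k x n_effects correlation matrix) and `n_used`
#'   (per-cell complete-pair counts).
#' @export
correlate_components_with_effects <- function(scores, clinical,
                                              k = min(3L, ncol(scores))) {
  stopifnot(inherits(clinical, "clinical_profile"))
  drugs <- align_drugs(rownames(scores), clinical$drugs,
                       "scores and clinical profile")
  S <- scores[drugs, seq_len(k), drop = FALSE]
  Y <- clinical$scores[drugs, , drop = FALSE]
  r <- matrix(NA_real_, k, ncol(Y),
              dimnames = list(colnames(S), colnames(Y)))
  n_used <- matrix(0L, k, ncol(Y), dimnames = dimnames(r))
  masked <- character(0)
  for (a in seq_len(k)) for (e in seq_len(ncol(Y))) {
    ok <- !is.na(Y[, e])
    n_used[a, e] <- sum(ok)
    if (sum(ok) < 3L || sd(Y[ok, e]) == 0 || sd(S[ok, a]) == 0) {
      masked <- c(masked, colnames(Y)[e])
      next
    }
    r[a, e] <- cor(S[ok, a], Y[ok, e])
  }
  if (length(masked) > 0)
    warning("correlate_components_with_effects: masked cell(s) with <3 ",
            "pairs or zero variance for effect(s): ",
            paste(unique(masked), collapse = ", "))
  list(r = r, n_used = n_used)
}

#' Mean clinical effect scores per cluster
#'
#' Per-cluster means over member drugs' observed effect values; no
#' imputation at this stage (imputation is reserved for prediction, where it
#' is confined to training folds). Cells where no member has an observed
#' value are masked.
#'
#' @param clinical a `clinical_profile`.
#' @param partition a `partition` or `grouping_scheme`.
#' @return list with `mean` (cluster x effect matrix) and `n_used`
#'   (per-cell observation counts).
#' @export
cluster_mean_effects <- function(clinical, partition) {
  stopifnot(inherits(clinical, "clinical_profile"))
  memb <- partition$assignment
  drugs <- align_drugs(clinical$drugs, names(memb),
                       "clinical profile and partition")
  Y <- clinical$scores[drugs, , drop = FALSE]
  memb <- memb[drugs]
  ids <- sort(unique(as.character(memb)))
  mean_tab <- matrix(NA_real_, length(ids), ncol(Y),
                     dimnames = list(ids, colnames(Y)))
  n_used <- matrix(0L, length(ids), ncol(Y), dimnames = dimnames(mean_tab))
  for (cid in ids) {
    rows <- which(memb == cid)
    for (e in seq_len(ncol(Y))) {
      v <- Y[rows, e]
      v <- v[!is.na(v)]
      n_used[cid, e] <- length(v)
      if (length(v) > 0) mean_tab[cid, e] <- mean(v)
    }
  }
  list(mean = mean_tab, n_used = n_used)
}
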