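# Predict: leave-one-drug-out PLS prediction of clinical effect profiles
# from any predictor set (full fingerprints or one-hot categorical
# groupings), with a permutation null for the summary median error.

#' Encode a predictor matrix
#'
#' Categorical grouping schemes are one-hot encoded (D = number of
#' categories, row sums 1); a completed adjusted affinity matrix passes
#' through unchanged (D = number of receptors).
#'
#' @param x a `grouping_scheme`, an `adjusted_matrix` without missing
#'   values, or a complete numeric matrix.
#' @param name optional source label override.
#' @return a `predictor_matrix`: list with `drugs`, `X` (n x D), `D`,
#'   `source`.
#' @export
encode_predictors <- function(x, name = NULL) {
  if (inherits(x, "grouping_scheme")) {
    if (x$n_categories == 1L)
      warning("encode_predictors: scheme '", x$name,
              "' has a single category; predictions reduce to the grand mean")
    labels <- sort(unique(x$assignment))
    X <- outer(x$assignment, labels, `==`) * 1
    dimnames(X) <- list(names(x$assignment), labels)
    src <- paste0("one_hot:", if (is.null(name)) x$name else name)
  } else {
    X <- as_values(x)
    if (anyNA(X))
      stop("encode_predictors: receptor-profile predictors contain missing ",
           "values; impute first")
    src <- if (is.null(name)) "receptor_profile" else name
  }
  structure(list(drugs = rownames(X), X = X, D = ncol(X), source = src),
            class = "predictor_matrix")
}

# lean NIPALS PLS2 core on pre-scaled matrices; returns D x k coefficient
# matrix B such that Yhat_scaled = Xs %*% B. Stops early (with fewer
# components) when X is fully deflated.
pls_nipals_core <- function(Xs, Ys, ncomp, tol = 1e-10, max_iter = 500L) {
  D <- ncol(Xs); k <- ncol(Ys)
  W <- matrix(0, D, 0); P <- matrix(0, D, 0); Q <- matrix(0, k, 0)
  for (a in seq_len(ncomp)) {
    yv <- colSums(Ys^2)
    if (max(yv) < tol) break
    u <- Ys[, which.max(yv)]
    w_old <- rep(0, D)
    w <- crossprod(Xs, u)
    for (it in seq_len(max_iter)) {
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tv <- Xs %*% w
      tt <- sum(tv^2)
      if (tt < tol) break
      qv <- crossprod(Ys, tv) / tt
      qq <- sum(qv^2)
      if (qq < tol) break
      u <- Ys %*% qv / qq
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
      w <- crossprod(Xs, u)
    }
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    tv <- Xs %*% w
    tt <- sum(tv^2)
    if (tt < tol) break
    qv <- crossprod(Ys, tv) / tt
    pv <- crossprod(Xs, tv) / tt
    Xs <- Xs - tv %*% t(pv)
    Ys <- Ys - tv %*% t(qv)
    W <- cbind(W, w); P <- cbind(P, pv); Q <- cbind(Q, qv)
  }
  if (ncol(W) == 0L) return(matrix(0, D, k))
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a multi-target PLS regression
#'
#' NIPALS PLS2 on column-centered, unit-scaled X and Y (constant columns
#' get scale 1 and therefore zero weight). Suited to many collinear
#' predictors and multiple simultaneous targets. At full rank the
#' predictions coincide with ordinary least squares.
#'
#' @param X n x D predictor matrix.
#' @param Y n x k target matrix.
#' @param n_components number of latent components; must satisfy
#'   `n_components <= min(D, n - 1)`. Fewer components are kept (silently)
#'   when X deflates to zero earlier, i.e. when its rank is lower.
#' @return a `pls_model` with centers, scales and the coefficient matrix.
#' @export
fit_pls <- function(X, Y, n_components = 2L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop("fit_pls: need at least 3 training rows")
  if (anyNA(X) || anyNA(Y)) stop("fit_pls: X and Y must be complete")
  if (n_components < 1L || n_components > min(ncol(X), n - 1L))
    stop("fit_pls: n_components must be in [1, min(D, n - 1)] = [1, ",
         min(ncol(X), n - 1L), "]")
  cx <- colMeans(X); cy <- colMeans(Y)
  sx <- apply(X, 2, sd); sy <- apply(Y, 2, sd)
  sx[!is.finite(sx) | sx < 1e-12] <- 1
  sy[!is.finite(sy) | sy < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, cx), 2, sx, `/`)
  Ys <- sweep(sweep(Y, 2, cy), 2, sy, `/`)
  B <- pls_nipals_core(Xs, Ys, n_components)
  structure(list(B = B, x_center = cx, x_scale = sx, y_center = cy,
                 y_scale = sy, n_components = n_components,
                 targets = colnames(Y)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = length(object$x_center))
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, `/`)
  Yh <- sweep(sweep(Xs %*% object$B, 2, object$y_scale, `*`), 2,
              object$y_center, `+`)
  colnames(Yh) <- object$targets
  Yh
}

#' Impute missing clinical effects within a training fold
#'
#' PPCA imputation of the training target matrix; the held-out drug never
#' enters. Observed entries are unchanged.
#'
#' @param Y training effect matrix with `NA`s (or a `clinical_profile`).
#' @param q PPCA rank (capped at `min(n, p) - 1`).
#' @param seed integer seed for the PPCA fit.
#' @return complete numeric matrix.
#' @export
impute_clinical_training <- function(Y, q = 2L, seed = 1L) {
  if (inherits(Y, "clinical_profile")) Y <- Y$scores
  if (any(colSums(!is.na(Y)) == 0L))
    stop("impute_clinical_training: effect column(s) fully missing in the ",
         "training data: ",
         paste(colnames(Y)[colSums(!is.na(Y)) == 0L], collapse = ", "))
  if (!anyNA(Y)) return(Y)
  q <- min(q, min(dim(Y)) - 1L)
  fit <- fit_ppca(Y, q = q, seed = seed, tol = 1e-7, max_iter = 500L)
  ppca_impute(fit, Y)
}

# shared LOO engine. Y_imp: list of per-fold imputed complete training
# matrices; perms: NULL (observed) or a list of per-fold training-row
# permutations (the null shuffles X rows against Y rows within training).
loo_errors_engine <- function(X, Y, obs_mask, Y_imp, usable, n_components,
                              perms = NULL) {
  n <- nrow(X)
  errs <- rep(NA_real_, n)
  for (i in which(usable)) {
    tr <- setdiff(seq_len(n), i)
    Xtr <- X[tr, , drop = FALSE]
    if (!is.null(perms)) Xtr <- Xtr[perms[[i]], , drop = FALSE]
    fit <- fit_pls(Xtr, Y_imp[[i]],
                   n_components = min(n_components, ncol(X), length(tr) - 1L))
    pred <- predict(fit, X[i, , drop = FALSE])
    ok <- obs_mask[i, ]
    errs[i] <- median(abs(pred[1, ok] - Y[i, ok]))
  }
  errs
}

#' Leave-one-drug-out median prediction error
#'
#' For each drug: fit PLS on all other drugs (with training-only PPCA
#' imputation of missing effects and training-only centering/scaling),
#' predict the held-out drug's effect scores, and take the median absolute
#' error over that drug's *observed* effects. The summary statistic is the
#' median of the per-drug medians (lower = better).
#'
#' @param predictors a `predictor_matrix` (see [encode_predictors()]).
#' @param clinical a `clinical_profile`.
#' @param n_components PLS components (capped per fold at
#'   `min(D, n_train - 1)`).
#' @param q_impute PPCA rank for training imputation.
#' @param seed integer seed.
#' @return a `prediction_report` (without a permutation null): `scheme`,
#'   `per_drug_errors`, `observed_median_error`.
#' @export
loo_median_error <- function(predictors, clinical, n_components = 2L,
                             q_impute = 2L, seed = 1L) {
  prep <- loo_prepare(predictors, clinical, q_impute, seed)
  errs <- loo_errors_engine(prep$X, prep$Y, prep$mask, prep$Y_imp,
                           prep$usable, n_components)
  structure(list(scheme = predictors$source, D = predictors$D,
                 per_drug_errors = stats::setNames(errs, prep$drugs),
                 observed_median_error = median(errs, na.rm = TRUE),
                 n_components = n_components, q_impute = q_impute,
                 seed = seed),
            class = "prediction_report")
}

loo_prepare <- function(predictors, clinical, q_impute, seed) {
  stopifnot(inherits(predictors, "predictor_matrix"),
            inherits(clinical, "clinical_profile"))
  drugs <- align_drugs(predictors$drugs, clinical$drugs,
                       "predictors and clinical profile")
  if (length(drugs) < 3L) stop("leave-one-out needs at least 3 shared drugs")
  X <- predictors$X[drugs, , drop = FALSE]
  Y <- clinical$scores[drugs, , drop = FALSE]
  mask <- !is.na(Y)
  usable <- rowSums(mask) > 0L
  if (any(!usable))
    warning("excluding drug(s) with no observed clinical effects: ",
            paste(drugs[!usable], collapse = ", "))
  seeds <- derive_seeds(seed, paste0("fold", seq_along(drugs)))
  # imputation depends on Y only, so each fold's imputed training matrix is
  # computed once and reused across permutation replicates
  Y_imp <- vector("list", length(drugs))
  for (i in which(usable)) {
    tr <- setdiff(seq_along(drugs), i)
    Y_imp[[i]] <- impute_clinical_training(Y[tr, , drop = FALSE],
                                           q = q_impute, seed = seeds[i])
  }
  list(drugs = drugs, X = X, Y = Y, mask = mask, usable = usable,
       Y_imp = Y_imp)
}

#' Permutation test of predictive validity
#'
#' Compares the observed leave-one-out median error against a null
#' distribution obtained by shuffling the drug-to-predictor alignment
#' within the training data (breaking the receptor/grouping-to-clinical
#' link while keeping each held-out pairing intact). Smaller error = better;
#' the p-value uses the add-one rule
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)` with ties counted.
#'
#' @inheritParams loo_median_error
#' @param n_perm number of permutation replicates (default 500).
#' @param shuffle `"per_fold"` (default; a fresh training permutation per
#'   LOO fold within each replicate) or `"global"` (one permutation of drug
#'   labels per replicate reused across folds).
#' @return a `prediction_report` with `null_median_errors`, `p_value`,
#'   `n_perm`.
#' @export
permutation_test <- function(predictors, clinical, n_perm = 500L,
                             n_components = 2L, q_impute = 2L, seed = 1L,
                             shuffle = c("per_fold", "global")) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1")
  prep <- loo_prepare(predictors, clinical, q_impute, seed)
  obs_errs <- loo_errors_engine(prep$X, prep$Y, prep$mask, prep$Y_imp,
                                prep$usable, n_components)
  observed <- median(obs_errs, na.rm = TRUE)
  n <- length(prep$drugs)
  perm_seed <- derive_seeds(seed, "permutations")
  set.seed(perm_seed)
  null_err <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    perms <- if (shuffle == "global") {
      gperm <- sample.int(n - 1L)
      rep(list(gperm), n)
    } else {
      lapply(seq_len(n), function(i) sample.int(n - 1L))
    }
    errs <- loo_errors_engine(prep$X, prep$Y, prep$mask, prep$Y_imp,
                              prep$usable, n_components, perms = perms)
    null_err[r] <- median(errs, na.rm = TRUE)
  }
  p <- (1 + sum(null_err <= observed + 1e-12)) / (1 + n_perm)
  structure(list(scheme = predictors$source, D = predictors$D,
                 per_drug_errors = stats::setNames(obs_errs, prep$drugs),
                 observed_median_error = observed,
                 null_median_errors = null_err, p_value = p,
                 n_perm = n_perm, n_components = n_components,
                 q_impute = q_impute, seed = seed, shuffle = shuffle),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction report for '%s' (D = %d):\n", x$scheme, x$D))
  cat(sprintf("  LOO median error: %.4f over %d drugs\n",
              x$observed_median_error, sum(!is.na(x$per_drug_errors))))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g (n_perm = %d, shuffle = %s)\n",
                x$p_value, x$n_perm, x$shuffle))
  invisible(x)
}
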