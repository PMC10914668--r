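# Probabilistic PCA with EM over missing entries.
#
# Model: x_i = mu + W z_i + eps,  z_i ~ N(0, I_q),  eps ~ N(0, sigma2 I_p).
# With missing cells the observed-data likelihood factorises over each row's
# observed coordinates; EM treats the latent z_i as hidden and sums sufficient
# statistics over observed cells only, which is the exact EM for the
# incomplete-data likelihood (no row deletion, no ad-hoc fill-in).

#' Fit probabilistic PCA by EM, tolerating missing entries
#'
#' @param x numeric matrix with `NA` for missing cells, or an
#'   `affinity_matrix`/`adjusted_matrix`.
#' @param q number of latent components, `1 <= q < min(n, p)`.
#' @param seed integer seed (used only by the `"random"` initialization; the
#'   default SVD initialization is deterministic, but the seed is always
#'   consumed so runs are reproducible either way).
#' @param tol convergence tolerance on the relative change of the
#'   observed-data log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param init `"svd"` (loadings from the SVD of the column-mean-imputed
#'   matrix; deterministic) or `"random"`.
#' @return a `ppca_model`: `mean` (length p), `loadings` (p x q, the EM
#'   solution `W`), `sigma2`, `q`, `converged`, `n_iter`,
#'   `log_likelihood_trace`, plus the rotated orthonormal principal `axes`
#'   (p x q, sign-fixed so each column's largest-magnitude entry is
#'   positive, ordered by explained variance) and the corresponding
#'   `rotation` applied to latent scores.
#' @export
fit_ppca <- function(x, q, seed = 1L, tol = 1e-6, max_iter = 1000L,
                     init = c("svd", "random")) {
  init <- match.arg(init)
  X <- as_values(x)
  n <- nrow(X); p <- ncol(X)
  if (!(q >= 1 && q < min(n, p)))
    stop("fit_ppca: q must satisfy 1 <= q < min(n, p) = ", min(n, p))
  O <- !is.na(X)
  if (any(rowSums(O) == 0L) || any(colSums(O) == 0L))
    stop("fit_ppca: every row and column needs at least one observed entry")
  set.seed(seed)

  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  Xf[!O] <- mu[col(X)][!O]
  sv <- svd(sweep(Xf, 2, mu), nu = 0, nv = q)
  d2 <- sv$d^2 / max(n - 1, 1)
  W <- if (init == "svd") {
    sv$v * rep(sqrt(pmax(d2[seq_len(q)], 1e-8)), each = p)
  } else {
    matrix(rnorm(p * q, sd = 0.1), p, q)
  }
  sigma2 <- max(mean(d2[-seq_len(q)]), 1e-6)
  if (!is.finite(sigma2)) sigma2 <- 1e-6

  n_obs <- sum(O)
  obs_idx <- lapply(seq_len(n), function(i) which(O[i, ]))
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  Ez <- matrix(0, n, q)

  loglik <- function(mu, W, sigma2) {
    ll <- 0
    for (i in seq_len(n)) {
      o <- obs_idx[[i]]
      Wo <- W[o, , drop = FALSE]
      r <- X[i, o] - mu[o]
      M <- crossprod(Wo) + diag(sigma2, q)
      cM <- chol(M)
      logdet <- (length(o) - q) * log(sigma2) + 2 * sum(log(diag(cM)))
      # quad = (r'r - Wr' M^{-1} Wr)/sigma2 via the Woodbury identity
      a <- backsolve(cM, crossprod(Wo, r), transpose = TRUE)
      quad <- (sum(r^2) - sum(a^2)) / sigma2
      ll <- ll - 0.5 * (length(o) * log(2 * pi) + logdet + quad)
    }
    ll
  }

  for (iter in seq_len(max_iter)) {
    # E-step: per-row posterior over z given the observed coordinates
    Vz <- vector("list", n)
    for (i in seq_len(n)) {
      o <- obs_idx[[i]]
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2, q)
      Minv <- chol2inv(chol(M))
      Ez[i, ] <- Minv %*% crossprod(Wo, X[i, o] - mu[o])
      Vz[[i]] <- sigma2 * Minv
    }
    # M-step: joint (mu_j, W_j) solve per feature over its observed rows
    W_new <- W; mu_new <- mu
    for (j in seq_len(p)) {
      rows <- which(O[, j])
      Ezj <- Ez[rows, , drop = FALSE]
      A <- crossprod(Ezj) + Reduce(`+`, Vz[rows])
      s <- colSums(Ezj)
      G <- rbind(c(length(rows), s), cbind(s, A))
      h <- c(sum(X[rows, j]), crossprod(Ezj, X[rows, j]))
      beta <- solve(G, h)
      mu_new[j] <- beta[1]
      W_new[j, ] <- beta[-1]
    }
    # sigma2: expected squared residual over observed cells
    ss <- 0
    for (i in seq_len(n)) {
      o <- obs_idx[[i]]
      Wo <- W_new[o, , drop = FALSE]
      r <- X[i, o] - mu_new[o] - as.vector(Wo %*% Ez[i, ])
      ss <- ss + sum(r^2) + sum((Wo %*% Vz[[i]]) * Wo)
    }
    mu <- mu_new; W <- W_new
    sigma2 <- max(ss / n_obs, 1e-12)

    ll <- loglik(mu, W, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L) {
      prev <- ll_trace[iter - 1L]
      if (abs(ll - prev) < tol * (abs(prev) + 1e-12)) { converged <- TRUE; break }
    }
  }

  # rotate to the ordered orthonormal principal-axis frame; fix signs so the
  # largest-|loading| entry of each axis is positive (run-to-run stability)
  sw <- svd(W)
  signs <- apply(sw$u, 2, function(u) {
    s <- sign(u[which.max(abs(u))]); if (s == 0) 1 else s
  })
  axes <- sweep(sw$u, 2, signs, `*`)
  rotation <- sweep(sw$v, 2, signs, `*`)
  rownames(axes) <- colnames(X)
  structure(list(mean = mu, loadings = W, sigma2 = sigma2, q = q,
                 converged = converged, n_iter = iter,
                 log_likelihood_trace = ll_trace,
                 axes = axes, axis_sv = sw$d, rotation = rotation),
            class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf("PPCA model: p = %d, q = %d, sigma2 = %.4g, %sconverged in %d EM iteration(s)\n",
              length(x$mean), x$q, x$sigma2, if (x$converged) "" else "NOT ",
              x$n_iter))
  invisible(x)
}

ppca_posterior_mean_z <- function(model, X, O = !is.na(X)) {
  q <- model$q
  Ez <- matrix(0, nrow(X), q)
  for (i in seq_len(nrow(X))) {
    o <- which(O[i, ])
    if (length(o) == 0L) next  # no evidence: posterior mean is the prior, 0
    Wo <- model$loadings[o, , drop = FALSE]
    M <- crossprod(Wo) + diag(model$sigma2, q)
    Ez[i, ] <- chol2inv(chol(M)) %*% crossprod(Wo, X[i, o] - model$mean[o])
  }
  Ez
}

#' Impute missing cells with the PPCA posterior predictive mean
#'
#' Missing cells are replaced by `mu + W E[z | observed]`; observed cells are
#' returned bit-identical to the input. A fully missing row is imputed to the
#' model mean.
#'
#' @param model a fitted `ppca_model`.
#' @param x matrix with `NA`s (or `affinity_matrix`/`adjusted_matrix`)
#'   with the same number of columns the model was fitted on.
#' @return an object of the same type as `x` with no missing cells.
#' @export
ppca_impute <- function(model, x) {
  X <- as_values(x)
  if (ncol(X) != length(model$mean))
    stop("ppca_impute: matrix has ", ncol(X), " columns but the model was ",
         "fitted on ", length(model$mean))
  O <- !is.na(X)
  if (all(O)) Xc <- X else {
    Ez <- ppca_posterior_mean_z(model, X, O)
    pred <- sweep(Ez %*% t(model$loadings), 2, model$mean, `+`)
    Xc <- X
    Xc[!O] <- pred[!O]
  }
  if (is.matrix(x)) return(Xc)
  out <- x
  out$values <- Xc
  out$observed_original <- x$observed
  out$observed <- !is.na(Xc)
  out
}

#' Latent component scores
#'
#' Posterior-mean latent coordinates of each row under the fitted model,
#' rotated into the orthonormal principal-axis frame and ordered by
#' explained variance (descending), with the same sign convention as the
#' model's `axes`.
#'
#' @param model a fitted `ppca_model`.
#' @param x complete data matrix (impute first; missing values are an error).
#' @return n x q score matrix.
#' @export
ppca_scores <- function(model, x) {
  X <- as_values(x)
  if (anyNA(X))
    stop("ppca_scores: data contain missing values; run ppca_impute() first")
  if (ncol(X) != length(model$mean))
    stop("ppca_scores: dimension mismatch")
  Ez <- ppca_posterior_mean_z(model, X, matrix(TRUE, nrow(X), ncol(X)))
  S <- Ez %*% model$rotation
  dimnames(S) <- list(rownames(X), paste0("component_", seq_len(model$q)))
  S
}

#' Per-component fraction of variance explained
#'
#' Computed from the eigen-spectrum of the covariance of the completed data
#' matrix: fraction_k = lambda_k / sum(lambda). The denominator is the total
#' variance of the completed matrix, so fractions over all `min(n-1, p)`
#' non-null components sum to 1.
#'
#' @param model a fitted `ppca_model` (supplies `q`, the number of leading
#'   fractions returned when `k = NULL`).
#' @param x complete data matrix (impute first).
#' @param k number of leading fractions to return; `NULL` means `model$q`.
#' @return numeric vector of variance fractions, non-increasing; the full
#'   spectrum's fractions are attached as `attr(, "all")`.
#' @export
variance_explained <- function(model, x, k = NULL) {
  X <- as_values(x)
  if (anyNA(X))
    stop("variance_explained: data contain missing values; impute first")
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  frac <- ev / sum(ev)
  if (is.null(k)) k <- model$q
  structure(frac[seq_len(min(k, length(frac)))], all = frac)
}
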