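ohe_scheme <- function(labels, drugs = sprintf("d%02d", seq_along(labels)),
                       name = "scheme") {
  grouping_scheme(stats::setNames(labels, drugs), name)
}

test_that("one-hot encoding has unit row sums and pass-through keeps D", {
  g <- ohe_scheme(rep(c("w", "x", "y", "z"), length.out = 27))
  pm <- encode_predictors(g)
  expect_equal(dim(pm$X), c(27L, 4L))
  expect_true(all(rowSums(pm$X) == 1))
  expect_equal(pm$D, 4L)
  expect_match(pm$source, "one_hot")
  V <- matrix(rnorm(27 * 42), 27, 42,
              dimnames = list(sprintf("d%02d", 1:27), sprintf("r%02d", 1:42)))
  pr <- encode_predictors(V)
  expect_equal(pr$D, 42L)
  expect_equal(pr$source, "receptor_profile")
  expect_warning(encode_predictors(ohe_scheme(rep("only", 5))), "single")
  Vna <- V; Vna[1, 1] <- NA
  expect_error(encode_predictors(Vna), "missing")
})

test_that("PLS reproduces exact linear structure and OLS at full rank", {
  set.seed(14)
  n <- 20; D <- 4; k <- 3
  X <- matrix(rnorm(n * D), n, D)
  B <- matrix(rnorm(D * k), D, k)
  Y <- X %*% B + 1
  fit <- fit_pls(X, Y, n_components = D)
  expect_lt(max(abs(predict(fit, X) - Y)), 1e-8)     # exact-fit limit
  # full-rank PLS predictions equal the least-squares oracle
  Yn <- Y + matrix(rnorm(n * k), n, k)
  fit2 <- fit_pls(X, Yn, n_components = D)
  Xnew <- matrix(rnorm(5 * D), 5, D)
  ols <- cbind(1, Xnew) %*% qr.solve(cbind(1, X), Yn)
  expect_lt(max(abs(predict(fit2, Xnew) - ols)), 1e-6)
  # permuting training rows leaves the fit unchanged
  perm <- sample(n)
  fit3 <- fit_pls(X[perm, ], Yn[perm, ], n_components = D)
  expect_lt(max(abs(fit3$B - fit2$B)), 1e-10)
})

test_that("PLS handles constant predictor columns and rejects bad ranks", {
  set.seed(15)
  X <- cbind(rnorm(10), rep(1, 10))
  Y <- cbind(2 * X[, 1] + rnorm(10, sd = 0.1))
  fit <- fit_pls(X, Y, n_components = 1)
  expect_equal(fit$B[2, 1], 0)        # constant column carries zero weight
  expect_error(fit_pls(X, Y, n_components = 3), "n_components")
  expect_error(fit_pls(X[1:2, ], Y[1:2, , drop = FALSE], 1), "at least 3")
})

test_that("PLS agrees with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(16)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- X %*% matrix(rnorm(6 * 4), 6, 4) + matrix(rnorm(30 * 4, sd = 0.5), 30, 4)
  colnames(Y) <- paste0("y", 1:4)
  fit <- fit_pls(X, Y, n_components = 2)
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  pred_mo <- predict(mo, newdata = X)$predict[, , 2]
  expect_lt(max(abs(predict(fit, X) - pred_mo)), 1e-6)
})

test_that("training imputation completes rank-1 structure and shields held-out rows", {
  Y <- outer(c(1, 2, 3, 4, 5), c(2, 1, 3))
  colnames(Y) <- paste0("e", 1:3)
  Ym <- Y; Ym[2, 3] <- NA
  Yc <- impute_clinical_training(Ym, q = 1, seed = 1)
  expect_equal(Yc[2, 3], Y[2, 3], tolerance = 1e-3)
  expect_identical(Yc[!is.na(Ym)], Y[!is.na(Ym)])
  expect_identical(impute_clinical_training(Y), Y)     # no missing: identity
  Yall <- Ym; Yall[, 2] <- NA
  expect_error(impute_clinical_training(Yall), "fully missing")
})

test_that("group-constant targets with one-hot predictors give zero LOO error", {
  labels <- rep(c("a", "b", "c"), each = 3)
  g <- ohe_scheme(labels, drugs = sprintf("d%02d", 1:9))
  Y <- cbind(eff1 = c(1, 1, 1, 5, 5, 5, 9, 9, 9),
             eff2 = c(2, 2, 2, 0, 0, 0, -4, -4, -4))
  rownames(Y) <- sprintf("d%02d", 1:9)
  rep_ <- loo_median_error(encode_predictors(g), make_clinical(Y),
                           n_components = 2)
  expect_lt(rep_$observed_median_error, 1e-10)
  expect_true(all(rep_$per_drug_errors < 1e-10))
})

test_that("a hand-enumerated two-group LOO case matches the frozen value", {
  # 4 drugs, 2 groups of 2, one PLS component = training group means:
  # hold out a1 -> predict (3,6), errors (2,4), median 3; a2 -> 3;
  # b1 -> errors (4,8), median 6; b2 -> 6; summary median = 4.5
  g <- ohe_scheme(c("A", "A", "B", "B"), drugs = c("a1", "a2", "b1", "b2"))
  Y <- rbind(a1 = c(1, 2), a2 = c(3, 6), b1 = c(10, 20), b2 = c(14, 28))
  colnames(Y) <- c("e1", "e2")
  rep_ <- loo_median_error(encode_predictors(g), make_clinical(Y),
                           n_components = 1)
  expect_equal(unname(rep_$per_drug_errors), c(3, 3, 6, 6), tolerance = 1e-10)
  expect_equal(rep_$observed_median_error, 4.5, tolerance = 1e-10)
})

test_that("pure-noise targets never reach zero error", {
  set.seed(17)
  g <- ohe_scheme(rep(c("a", "b", "c"), each = 4))
  Y <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(sprintf("d%02d", 1:12),
                                                    paste0("e", 1:5)))
  rep_ <- loo_median_error(encode_predictors(g), make_clinical(Y))
  expect_gt(rep_$observed_median_error, 0.05)
  expect_lt(rep_$observed_median_error, 3)   # scale of median |N(0, ~1)|
})

test_that("held-out clinical values cannot leak into their own prediction", {
  set.seed(18)
  g <- ohe_scheme(rep(c("a", "b"), each = 4))
  # single effect so the held-out prediction is recoverable from the error:
  # err = |pred - y|; after poisoning y by +100 (with |pred - y| < 100),
  # err' = 100 -+ err iff the prediction did not move
  Y <- matrix(rnorm(8), 8, 1, dimnames = list(sprintf("d%02d", 1:8), "e1"))
  pm <- encode_predictors(g)
  base <- loo_median_error(pm, make_clinical(Y), seed = 5)
  Yp <- Y
  Yp["d05", ] <- Y["d05", ] + 100
  pois <- loo_median_error(pm, make_clinical(Yp), seed = 5)
  e0 <- base$per_drug_errors[["d05"]]
  e1 <- pois$per_drug_errors[["d05"]]
  expect_lt(min(abs(e1 - (100 - e0)), abs(e1 - (100 + e0))), 1e-8)
  # training-fold imputation is equally blind to the held-out drug's targets
  Ym <- cbind(Y, e2 = rnorm(8)); Ym[2, 2] <- NA
  Yq <- Ym; Yq["d05", ] <- -Ym["d05", ]
  prep1 <- apclust:::loo_prepare(pm, make_clinical(Ym), 2L, 5L)
  prep2 <- apclust:::loo_prepare(pm, make_clinical(Yq), 2L, 5L)
  i <- which(prep1$drugs == "d05")
  expect_identical(prep1$Y_imp[[i]], prep2$Y_imp[[i]])
})

test_that("permutation p-values follow the add-one rule and are reproducible", {
  set.seed(19)
  # strong signal: group-constant targets -> observed error 0 beats all nulls
  g <- ohe_scheme(rep(c("a", "b", "c"), each = 3), sprintf("d%02d", 1:9))
  Y <- cbind(e1 = rep(c(0, 5, 9), each = 3) + rnorm(9, sd = 0.01),
             e2 = rep(c(3, -2, 1), each = 3) + rnorm(9, sd = 0.01))
  rownames(Y) <- sprintf("d%02d", 1:9)
  rep_ <- permutation_test(encode_predictors(g), make_clinical(Y),
                           n_perm = 49, n_components = 2, seed = 3)
  expect_equal(rep_$p_value, 1 / 50)
  expect_length(rep_$null_median_errors, 49L)
  expect_gt(min(rep_$null_median_errors), rep_$observed_median_error)
  rep2 <- permutation_test(encode_predictors(g), make_clinical(Y),
                           n_perm = 49, n_components = 2, seed = 3)
  expect_identical(rep_$null_median_errors, rep2$null_median_errors)
  expect_identical(rep_$p_value, rep2$p_value)
  expect_error(permutation_test(encode_predictors(g), make_clinical(Y),
                                n_perm = 0), "n_perm")
})

test_that("an uninformative predictor yields a mid-range p-value", {
  set.seed(20)
  g <- ohe_scheme(rep(c("a", "b", "c", "d"), 3), sprintf("d%02d", 1:12))
  Y <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(sprintf("d%02d", 1:12),
                                                    paste0("e", 1:4)))
  rep_ <- permutation_test(encode_predictors(g), make_clinical(Y),
                           n_perm = 99, seed = 11)
  expect_gt(rep_$p_value, 0.05)
  # global-shuffle variant also runs and returns a valid p
  repg <- permutation_test(encode_predictors(g), make_clinical(Y),
                           n_perm = 19, seed = 11, shuffle = "global")
  expect_true(repg$p_value > 0 && repg$p_value <= 1)
})
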