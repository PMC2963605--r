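# Independent lasso oracle: glmnet's penalized coordinate descent in the
# lambda form, mapped onto the constraint form by bisection on the L1 norm.
glmnet_at_l1 <- function(U, y, target_l1, tol = 1e-9) {
  fit_at <- function(lambda) {
    f <- glmnet::glmnet(U, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14, maxit = 1e7)
    as.numeric(f$beta)
  }
  if (target_l1 <= 0) return(rep(0, ncol(U)))
  lo <- 0
  hi <- max(abs(crossprod(U, y - mean(y)))) / nrow(U)  # null-model lambda
  # bisect lambda so that sum|beta(lambda)| = target_l1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    b <- fit_at(mid)
    l1 <- sum(abs(b))
    if (abs(l1 - target_l1) < tol) break
    if (l1 > target_l1) lo <- mid else hi <- mid
  }
  b
}

make_regression <- function(n, p, seed, collinear = FALSE) {
  set.seed(seed)
  U <- matrix(rnorm(n * p), n, p)
  if (collinear) U[, p] <- U[, 1] + rnorm(n, 0, 1e-6)
  beta <- numeric(p)
  beta[sample(p, ceiling(p / 2))] <- rnorm(ceiling(p / 2), 0, 2)
  y <- drop(U %*% beta) + rnorm(n, 0, 0.5)
  list(U = scale(U), y = y)
}

test_that("the lasso path endpoint is OLS and the origin is the null model", {
  d <- make_regression(60, 6, seed = 1)
  Uc <- scale(d$U, scale = FALSE)
  yc <- d$y - mean(d$y)
  path <- grnpipe:::lars_lasso_path(Uc, yc)
  b_ols <- qr.coef(qr(Uc), yc)
  expect_equal(unname(path[nrow(path), ]), unname(b_ols), tolerance = 1e-8)
  expect_equal(path[1, ], rep(0, 6))
})

test_that("path L1 norms are non-decreasing along the path", {
  for (seed in 1:5) {
    d <- make_regression(50, 8, seed)
    Uc <- scale(d$U, scale = FALSE)
    yc <- d$y - mean(d$y)
    path <- grnpipe:::lars_lasso_path(Uc, yc)
    l1 <- rowSums(abs(path))
    expect_true(all(diff(l1) > -1e-10))
  }
})

test_that("the path solution matches the coordinate-descent oracle", {
  for (seed in 1:3) {
    d <- make_regression(80, 8, seed)
    Uc <- scale(d$U, scale = FALSE)
    yc <- d$y - mean(d$y)
    b_ols <- qr.coef(qr(Uc), yc)
    path <- grnpipe:::lars_lasso_path(Uc, yc)
    for (s in c(0.2, 0.5, 0.8)) {
      target <- s * sum(abs(b_ols))
      mine <- grnpipe:::path_coef_at_l1(path, target)
      oracle <- glmnet_at_l1(Uc, yc, target)
      expect_equal(unname(mine), oracle, tolerance = 1e-6)
    }
  }
})

test_that("s = 1 returns OLS and s = 0 the bias-only model", {
  d <- make_regression(60, 5, seed = 7)
  X_cand <- t(d$U)
  rownames(X_cand) <- paste0("G", 1:5)
  fit1 <- fit_gene_model(d$y, X_cand, s_grid = 1, seed = 2)
  Uc <- scale(d$U, scale = FALSE)
  b_ols <- qr.coef(qr(Uc), d$y - mean(d$y))
  expect_equal(unname(fit1$beta), unname(b_ols), tolerance = 1e-7)

  fit0 <- fit_gene_model(d$y, X_cand, s_grid = 0, seed = 2)
  expect_true(all(fit0$beta == 0))
  expect_equal(fit0$bias, mean(d$y))
})

test_that("a single binding predictor shrinks linearly in s", {
  set.seed(3)
  u <- as.numeric(scale(rnorm(50)))
  y <- 2 * u + rnorm(50, 0, 0.1)
  X_cand <- matrix(u, 1, 50, dimnames = list("G1", NULL))
  uc <- u - mean(u)
  b_ols <- sum(uc * (y - mean(y))) / sum(uc^2)
  for (s in c(0.25, 0.5, 0.75)) {
    fit <- fit_gene_model(y, X_cand, s_grid = s, seed = 1)
    expect_equal(unname(fit$beta), sign(b_ols) * s * abs(b_ols),
                 tolerance = 1e-9)
  }
})

test_that("cross-validation applies the one-SD rule toward sparser models", {
  d <- make_regression(100, 6, seed = 9)
  X_cand <- t(d$U); rownames(X_cand) <- paste0("G", 1:6)
  fit <- fit_gene_model(d$y, X_cand, seed = 5)
  curve <- fit$cv_curve
  k_min <- which.min(curve$mean)
  thresh <- curve$mean[k_min] + curve$sd[k_min]
  k_hat <- which(curve$s == fit$s_hat)
  expect_lte(curve$mean[k_hat], thresh)
  # no smaller s on the grid also satisfies the threshold
  if (k_hat > 1) expect_true(all(curve$mean[seq_len(k_hat - 1)] > thresh))
  # constraint holds: sum|beta| <= s_hat * sum|beta_OLS| (+ numerical slack)
  Uc <- scale(d$U, scale = FALSE)
  b_ols <- qr.coef(qr(Uc), d$y - mean(d$y))
  expect_lte(sum(abs(fit$beta)), fit$s_hat * sum(abs(b_ols)) + 1e-9)
})

test_that("explanatory power hits its limit cases", {
  y <- rnorm(30)
  expect_equal(explanatory_power(0, y), 1)                 # perfect CV
  expect_equal(explanatory_power(sum((y - mean(y))^2), y), 0)  # null model
  expect_equal(explanatory_power(2 * sum((y - mean(y))^2), y), 0)  # clipped
  expect_equal(explanatory_power(10, rep(1, 30)), 0)       # zero variance
})

test_that("candidate selection filters, sorts and truncates deterministically", {
  genes <- paste0("G", 1:5)
  Z <- matrix(0, 5, 5, dimnames = list(genes, genes))
  Z[1, 2:5] <- c(0.5, 2, 2, 1)   # tie between G3 and G4
  cand <- select_candidates(Z, K = 3)
  expect_equal(cand$G1, c("G3", "G4", "G5"))  # tie broken by index; top 3
  expect_equal(cand$G2, character(0))          # all-zero row -> empty

  mask <- matrix(TRUE, 5, 5); mask[1, 3] <- FALSE
  cand2 <- select_candidates(Z, mask, K = 3)
  expect_equal(cand2$G1, c("G4", "G5", "G2"))
})

test_that("gene fits assemble into a dynamical model with zero empty rows", {
  lin <- simulate_linear_dataset(n_genes = 6, seed = 12)
  rd <- build_response_design(lin$ts, list(lin$wt), lags = 1)
  genes <- lin$net$genes
  cand <- lapply(setNames(genes, genes), function(g) character(0))
  cand$G1 <- setdiff(genes, "G1")[1:2]
  res <- inferelator_fit(rd, cand, K_folds = 5, seed = 3)
  expect_true(all(res$model$beta[2:6, ] == 0))
  expect_equal(unname(res$model$h[2:6]), rep(0, 5))
  expect_equal(res$model$alpha, rd$alpha)
})

test_that("edge confidences follow the weighted-average formula", {
  genes <- c("G1", "G2", "G3")
  beta <- matrix(0, 3, 3, dimnames = list(genes, genes))
  model <- structure(list(beta = beta, bias = setNames(c(0, 0, 0), genes),
                          h = setNames(c(1, 1, 0.5), genes), alpha = 0.01,
                          regressor_stats = NULL), class = "dynamical_model")
  # single regulator, zero bias, h = 1 -> confidence 1
  model$beta[1, 2] <- 0.7
  Z <- inferelator_confidences(model)
  expect_equal(Z["G1", "G2"], 1)
  # two regulators with |beta| ratio 3:1 -> scores in ratio 3:1
  model$beta[2, 1] <- -3; model$beta[2, 3] <- 1
  Z <- inferelator_confidences(model)
  expect_equal(Z["G2", "G1"] / Z["G2", "G3"], 3)
  expect_equal(Z["G2", "G1"] + Z["G2", "G3"], 1)  # h = 1, zero bias
  # h = 0 zeroes the row
  model$h[["G2"]] <- 0
  Z <- inferelator_confidences(model)
  expect_true(all(Z["G2", ] == 0))
})

test_that("zero-noise parameter recovery is exact at s = 1 with true candidates", {
  lin <- simulate_linear_dataset(n_genes = 8, n_series = 6, seed = 21)
  rd <- build_response_design(lin$ts, list(lin$wt), lags = 1)
  genes <- lin$net$genes
  W <- lin$net$adjacency
  cand <- lapply(setNames(seq_along(genes), genes), function(i) {
    genes[W[i, ] != 0]
  })
  res <- inferelator_fit(rd, cand, s_grid = 1, seed = 2)
  # fitted model reproduces the response matrix
  std <- standardize_explanatory(rd$X)
  pred <- res$model$beta %*% std$X_std + res$model$bias
  expect_lt(max(abs(pred - rd$Y)), 1e-6)
})
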