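#' Select candidate regulators per gene from tlCLR confidences
#'
#' For each target gene, candidate regulators are those with a strictly
#' positive tlCLR confidence that also survive the MCZ percentile filter,
#' sorted by confidence descending and truncated to the `K` best.  Ties at
#' the cut are broken by gene index so the selection is deterministic.  Not
#' every gene is guaranteed `K` candidates; an empty list yields a
#' bias-only model downstream.
#'
#' @param Z_tlclr tlCLR confidence matrix (rows targets, cols regulators).
#' @param mcz_mask Optional logical mask from [mcz_filter_mask()]; `NULL`
#'   disables filtering.
#' @param K Maximum number of candidates per gene (default 10).
#' @return Named list (one entry per target gene) of regulator id vectors.
#' @export
select_candidates <- function(Z_tlclr, mcz_mask = NULL, K = 10L) {
  stopifnot(K >= 1L)
  n <- nrow(Z_tlclr)
  genes <- rownames(Z_tlclr)
  if (is.null(genes)) genes <- gene_labels(n)
  out <- vector("list", n)
  names(out) <- genes
  for (i in seq_len(n)) {
    score <- Z_tlclr[i, ]
    ok <- score > 0
    ok[i] <- FALSE
    if (!is.null(mcz_mask)) ok <- ok & mcz_mask[i, ]
    j <- which(ok)
    j <- j[order(-score[j], j)]
    out[[i]] <- genes[utils::head(j, K)]
  }
  out
}

# LARS with the lasso modification (Efron et al.): piecewise-linear
# coefficient path from the null model to OLS.  `U` has centered columns,
# `y` is centered.  All updates are done in Gram-matrix space, so each
# step costs O(p^2) regardless of the number of observations.  Returns a
# steps x p matrix of coefficient breakpoints.
lars_lasso_path <- function(U, y, eps = 1e-10, max_steps = NULL,
                            gram = NULL, Uty = NULL) {
  p <- ncol(U)
  if (p == 0L) return(matrix(0, 1L, 0L))
  if (is.null(max_steps)) max_steps <- 8L * p + 10L
  if (is.null(gram)) gram <- crossprod(U)
  if (is.null(Uty)) Uty <- drop(crossprod(U, y))
  beta <- numeric(p)
  active <- integer(0)
  in_active <- logical(p)
  path <- list(beta)
  for (step in seq_len(max_steps)) {
    cvec <- Uty - drop(gram %*% beta)
    C <- max(abs(cvec))
    if (C < eps) break
    if (length(active) < p) {
      inactive <- which(!in_active)
      entrant <- inactive[which.max(abs(cvec[inactive]))]
      if (length(active) == 0L || abs(cvec[entrant]) >= C - eps * max(1, C)) {
        active <- c(active, entrant)
        in_active[entrant] <- TRUE
      }
    }
    s <- sign(cvec[active])
    G <- gram[active, active, drop = FALSE]
    Ginv_s <- tryCatch(solve(G, s), error = function(e) {
      solve(G + diag(1e-10, length(active)), s)
    })
    A <- 1 / sqrt(sum(s * Ginv_s))
    d <- A * Ginv_s   # coefficient direction in original coordinates
    a <- drop(gram[, active, drop = FALSE] %*% d)  # U' (equiangular dir)
    gamma <- C / A                        # full step to joint OLS
    inactive <- which(!in_active)
    for (j in inactive) {
      for (g in c((C - cvec[[j]]) / (A - a[[j]]),
                  (C + cvec[[j]]) / (A + a[[j]]))) {
        if (is.finite(g) && g > eps && g < gamma) gamma <- g
      }
    }
    # lasso modification: drop a variable whose coefficient hits zero first
    drop_j <- 0L
    for (k in seq_along(active)) {
      if (d[[k]] != 0) {
        g <- -beta[[active[[k]]]] / d[[k]]
        if (g > eps && g < gamma) {
          gamma <- g
          drop_j <- k
        }
      }
    }
    beta[active] <- beta[active] + gamma * d
    if (drop_j > 0L) {
      beta[[active[[drop_j]]]] <- 0
      in_active[active[[drop_j]]] <- FALSE
      active <- active[-drop_j]
    }
    path[[length(path) + 1L]] <- beta
  }
  do.call(rbind, path)
}

# Coefficients on the lasso path at a requested L1 norm (linear
# interpolation between breakpoints, as the path is piecewise linear).
path_coef_at_l1 <- function(path, target) {
  l1 <- rowSums(abs(path))
  k <- nrow(path)
  if (target <= 0) return(path[1L, ])
  if (target >= l1[[k]]) return(path[k, ])
  hi <- which(l1 >= target)[[1L]]
  if (hi == 1L) return(path[1L, ])
  lo <- hi - 1L
  frac <- (target - l1[[lo]]) / (l1[[hi]] - l1[[lo]])
  path[lo, ] + frac * (path[hi, ] - path[lo, ])
}

# OLS L1-norm reference for the shrinkage constraint; ridge-stabilized when
# the design is rank deficient.
ols_reference <- function(U, y, ridge_eps = 1e-8) {
  p <- ncol(U)
  if (p == 0L) return(numeric(0))
  qrU <- qr(U)
  if (qrU$rank < p) {
    solve(crossprod(U) + diag(ridge_eps, p), crossprod(U, y))
  } else {
    qr.coef(qrU, y)
  }
}

# Constraint-form lasso solve: coefficients with L1 norm s * ||beta_OLS||_1.
lasso_at_s <- function(U, y, s) {
  b_ols <- ols_reference(U, y)
  path <- lars_lasso_path(U, y)
  drop(path_coef_at_l1(path, s * sum(abs(b_ols))))
}

#' Explanatory power of a gene's regression model
#'
#' One minus the relative cross-validated prediction error, clipped to
#' `[0, 1]`: `h = clip(1 - CV_SSE / sum((y - mean(y))^2), 0, 1)`.  A model
#' no better than the mean has `h = 0`; a perfectly predictive model has
#' `h = 1`.  Zero-variance responses score 0.
#'
#' @param cv_sse Cross-validated sum of squared prediction errors.
#' @param y Response vector the model was fit to.
#' @return Explanatory power in `[0, 1]`.
#' @export
explanatory_power <- function(cv_sse, y) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(0)
  min(max(1 - cv_sse / tss, 0), 1)
}

#' Fit an L1-constrained dynamical model for one gene
#'
#' Minimizes the squared error of the ODE response against the candidate
#' regulators subject to an L1 constraint expressed as a fraction `s` of
#' the ordinary-least-squares coefficient norm (`s = 1` is OLS, `s = 0` the
#' bias-only model), solved along the LARS-lasso path.  The shrinkage
#' fraction is chosen by K-fold cross-validation (contiguous folds after a
#' seeded shuffle) with the one-standard-deviation rule: the smallest `s`
#' whose mean CV error is within one standard deviation of the minimum,
#' favouring sparse models to avoid overfitting.  The final model is refit
#' on all observations at the chosen `s`.
#'
#' @param y Length-n response vector (not standardized; its scale carries
#'   the degradation rate).
#' @param X_cand Candidates x observations matrix of standardized
#'   regulator profiles.
#' @param K_folds Number of CV folds (default 10).
#' @param s_grid Shrinkage grid in `[0, 1]` (default steps of 0.05).
#' @param seed Seed for the CV fold shuffle.
#' @return A `gene_fit` list: `candidates`, `beta` (named, standardized
#'   scale), `bias`, `s_hat`, `cv_curve` (per-s mean and sd of CV error),
#'   `h` (explanatory power), `cv_sse`.
#' @export
fit_gene_model <- function(y, X_cand, K_folds = 10L,
                           s_grid = seq(0, 1, by = 0.05), seed = 1L) {
  cand <- rownames(X_cand)
  p <- nrow(X_cand)
  n <- length(y)
  null_fit <- function() {
    structure(list(candidates = character(0),
                   beta = stats::setNames(numeric(0), character(0)),
                   bias = mean(y), s_hat = 0, cv_curve = NULL, h = 0,
                   cv_sse = sum((y - mean(y))^2)),
              class = "gene_fit")
  }
  if (p == 0L || stats::sd(y) == 0) return(null_fit())
  if (n < K_folds) {
    stop("fewer observations than CV folds", call. = FALSE)
  }
  U_all <- t(X_cand)                      # n x p
  # contiguous, near-equal fold blocks over a seeded shuffle
  fold_of <- with_seed(seed, {
    sizes <- diff(round(seq(0, n, length.out = K_folds + 1)))
    f <- integer(n)
    f[sample.int(n)] <- rep(seq_len(K_folds), times = sizes)
    f
  })
  n_s <- length(s_grid)
  fold_mse <- matrix(NA_real_, K_folds, n_s)
  fold_sse <- matrix(NA_real_, K_folds, n_s)
  for (f in seq_len(K_folds)) {
    test <- fold_of == f
    U_tr <- U_all[!test, , drop = FALSE]
    y_tr <- y[!test]
    mu_u <- colMeans(U_tr)
    mu_y <- mean(y_tr)
    U_c <- sweep(U_tr, 2L, mu_u)
    y_c <- y_tr - mu_y
    b_ols <- ols_reference(U_c, y_c)
    path <- lars_lasso_path(U_c, y_c)
    l1_ref <- sum(abs(b_ols))
    U_te <- sweep(U_all[test, , drop = FALSE], 2L, mu_u)
    y_te <- y[test]
    for (k in seq_len(n_s)) {
      b <- path_coef_at_l1(path, s_grid[[k]] * l1_ref)
      resid <- y_te - (mu_y + drop(U_te %*% b))
      fold_sse[f, k] <- sum(resid^2)
      fold_mse[f, k] <- mean(resid^2)
    }
  }
  mean_err <- colMeans(fold_mse)
  sd_err <- apply(fold_mse, 2L, stats::sd)
  k_min <- which.min(mean_err)
  ok <- mean_err <= mean_err[[k_min]] + sd_err[[k_min]]
  k_hat <- which(ok)[[1L]]                # smallest s: sparsest acceptable
  s_hat <- s_grid[[k_hat]]
  cv_sse <- sum(fold_sse[, k_hat])
  h <- explanatory_power(cv_sse, y)
  # final fit on all observations at s_hat
  mu_u <- colMeans(U_all)
  mu_y <- mean(y)
  U_c <- sweep(U_all, 2L, mu_u)
  b_ols <- ols_reference(U_c, y - mu_y)
  path <- lars_lasso_path(U_c, y - mu_y)
  beta <- drop(path_coef_at_l1(path, s_hat * sum(abs(b_ols))))
  names(beta) <- cand
  structure(list(candidates = cand, beta = beta,
                 bias = mu_y - sum(mu_u * beta), s_hat = s_hat,
                 cv_curve = data.frame(s = s_grid, mean = mean_err,
                                       sd = sd_err),
                 h = h, cv_sse = cv_sse),
            class = "gene_fit")
}

#' Fit dynamical models for every gene
#'
#' Standardizes the explanatory matrix, fits one L1-constrained model per
#' target gene on its candidate regulators (constant regulators excluded),
#' and assembles the results into a network-wide dynamical model.
#'
#' @param rd A [build_response_design()] object.
#' @param candidates Per-gene candidate lists from [select_candidates()].
#' @param K_folds,s_grid,seed Passed to [fit_gene_model()]; per-gene seeds
#'   are derived as `seed + gene index`.
#' @return A list: `fits` (per-gene `gene_fit`s) and `model`, a
#'   `dynamical_model` with `beta` (N x N sparse weight matrix on the
#'   standardized-regulator scale), `bias`, `h`, `alpha`,
#'   `regressor_stats` (per-regulator mean/sd for de-standardization).
#' @export
inferelator_fit <- function(rd, candidates, K_folds = 10L,
                            s_grid = seq(0, 1, by = 0.05), seed = 1L) {
  std <- standardize_explanatory(rd$X)
  genes <- rd$genes
  n <- length(genes)
  usable <- genes[!std$stats$constant]
  fits <- vector("list", n)
  names(fits) <- genes
  beta <- matrix(0, n, n, dimnames = list(genes, genes))
  bias <- stats::setNames(numeric(n), genes)
  h <- stats::setNames(numeric(n), genes)
  for (i in seq_len(n)) {
    cand <- intersect(candidates[[genes[[i]]]], usable)
    fit <- fit_gene_model(rd$Y[i, ],
                          std$X_std[cand, , drop = FALSE],
                          K_folds = K_folds, s_grid = s_grid,
                          seed = seed + i)
    fits[[i]] <- fit
    if (length(fit$beta)) beta[i, names(fit$beta)] <- fit$beta
    bias[[i]] <- fit$bias
    h[[i]] <- fit$h
  }
  model <- structure(list(beta = beta, bias = bias, h = h, alpha = rd$alpha,
                          regressor_stats = std$stats),
                     class = "dynamical_model")
  list(fits = fits, model = model)
}

#' Edge confidences from fitted dynamical models
#'
#' The confidence of the interaction regulator j -> target i distributes
#' target i's explanatory power over its model terms in proportion to
#' coefficient magnitude (regulators are comparable because they were
#' standardized before selection):
#' `Z(i, j) = h_i * |beta_ij| / (|bias_i| + sum_k |beta_ik|)`.
#' Genes whose denominator is zero contribute a row of zeros.
#'
#' @param model A `dynamical_model` from [inferelator_fit()].
#' @return N x N confidence matrix (rows targets, columns regulators).
#' @export
inferelator_confidences <- function(model) {
  n <- nrow(model$beta)
  denom <- abs(model$bias) + rowSums(abs(model$beta))
  Z <- abs(model$beta) * model$h / ifelse(denom > 0, denom, Inf)
  diag(Z) <- 0
  dimnames(Z) <- dimnames(model$beta)
  Z
}
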