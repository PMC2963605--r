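#' Bootstrap the columns of a response design
#'
#' Observations (columns) are drawn with replacement, the same index vector
#' applied to the response and explanatory matrices so the pairing between
#' a response value and its time-lagged explanatory value is never broken.
#' Column kind tags are carried along.
#'
#' @param rd A [build_response_design()] object.
#' @param seed Integer seed; the same seed reproduces the same resample.
#' @return A `response_design` with the same number of columns.
#' @export
bootstrap_columns <- function(rd, seed = 1L) {
  n_obs <- ncol(rd$Y)
  idx <- with_seed(seed, sample.int(n_obs, n_obs, replace = TRUE))
  out <- rd
  out$Y <- rd$Y[, idx, drop = FALSE]
  out$X <- rd$X[, idx, drop = FALSE]
  out$obs_kind <- rd$obs_kind[idx]
  out
}

# One tlCLR -> Inferelator -> combine pass over a (possibly resampled)
# design, with the MCZ matrix held fixed.  Static MI is computed from the
# design's explanatory matrix so a resample sees resampled backgrounds.
pipeline3_member <- function(rd, Z_mcz, mcz_mask, K = 10L, K_folds = 10L,
                             s_grid = seq(0, 1, by = 0.05), n_bins = 10L,
                             seed = 1L) {
  M_stat <- static_mi_matrix(rd$X, n_bins = n_bins)
  M_dyn <- dynamic_mi_matrix(rd, n_bins = n_bins)
  Z_tlclr <- tlclr_scores(M_dyn, M_stat)
  cand <- select_candidates(Z_tlclr, mcz_mask, K = K)
  fit <- inferelator_fit(rd, cand, K_folds = K_folds, s_grid = s_grid,
                         seed = seed)
  Z_inf <- inferelator_confidences(fit$model)
  Z_p2 <- pipeline2_combine(Z_tlclr, Z_inf)
  Z_p3 <- pipeline3_combine(Z_p2, Z_mcz)
  list(Z_tlclr = Z_tlclr, Z_inf = Z_inf, Z_p2 = Z_p2, Z_p3 = Z_p3,
       model = fit$model, fits = fit$fits)
}

#' Pipeline 4: resampling ensemble of pipeline-3 networks
#'
#' Repeats pipeline 3 on `M` column bootstraps of the response design.
#' Within each resample the tlCLR and Inferelator stages are recomputed
#' from the resampled observations, while the MCZ ranks — which come from
#' the knock-out design, not the resampled columns — remain constant.
#' Per-member seeds are derived as `seed + m`, so members are reproducible
#' and independent of evaluation order.
#'
#' @param rd A [build_response_design()] object.
#' @param Z_mcz Fixed MCZ confidence matrix.
#' @param mcz_mask Logical filter mask from [mcz_filter_mask()] (or
#'   `NULL`).
#' @param M Number of resamples (default 200).
#' @param K,K_folds,s_grid,n_bins Passed through to the member pipeline.
#' @param seed Base seed.
#' @param resampler Function `(rd, seed) -> response_design` used to draw
#'   each member's data; defaults to [bootstrap_columns()].  Supplying
#'   `function(rd, seed) rd` forces identity resamples, in which case every
#'   member equals the non-resampled pipeline-3 run.
#' @return A `network_ensemble` list: `members` (each with `Z_p3` and
#'   `model`), `M`, `seed`.
#' @export
run_resampling_pipeline <- function(rd, Z_mcz, mcz_mask = NULL, M = 200L,
                                    K = 10L, K_folds = 10L,
                                    s_grid = seq(0, 1, by = 0.05),
                                    n_bins = 10L, seed = 1L,
                                    resampler = bootstrap_columns) {
  stopifnot(M >= 1L)
  members <- vector("list", M)
  for (m in seq_len(M)) {
    rd_m <- resampler(rd, seed + m)
    res <- pipeline3_member(rd_m, Z_mcz, mcz_mask, K = K, K_folds = K_folds,
                            s_grid = s_grid, n_bins = n_bins, seed = seed + m)
    members[[m]] <- list(Z_p3 = res$Z_p3, model = res$model)
  }
  structure(list(members = members, M = M, seed = as.integer(seed)),
            class = "network_ensemble")
}

#' Median-rank confidences and median dynamical model from an ensemble
#'
#' Every regulatory interaction is ranked within each member's confidence
#' matrix (1 = most confident, ties get average ranks) and assigned the
#' median rank over members, mapped back to a positive confidence as
#' `P + 1 - median_rank` where `P = N(N-1)`.  The median dynamical model
#' takes the element-wise median of each coefficient over members — zeros
#' from members that dropped an edge included, which is what keeps the
#' ensemble median sparse — and likewise medians the bias and explanatory
#' power.
#'
#' @param ensemble A `network_ensemble` from [run_resampling_pipeline()].
#' @return A list: `Z` (median-rank confidence matrix) and `model`
#'   (median `dynamical_model`).
#' @export
ensemble_medians <- function(ensemble) {
  members <- ensemble$members
  M <- length(members)
  Z1 <- members[[1L]]$Z_p3
  n <- nrow(Z1)
  off <- which(offdiag_mask(n))
  P <- length(off)
  ranks <- sapply(members, function(m) rank(-m$Z_p3[off], ties.method = "average"))
  med_rank <- apply(matrix(ranks, nrow = P), 1L, stats::median)
  Z <- matrix(0, n, n, dimnames = dimnames(Z1))
  Z[off] <- P + 1 - med_rank
  beta_med <- apply(array(sapply(members, function(m) m$model$beta),
                          dim = c(n, n, M)), c(1L, 2L), stats::median)
  dimnames(beta_med) <- dimnames(members[[1L]]$model$beta)
  bias_med <- apply(sapply(members, function(m) m$model$bias), 1L,
                    stats::median)
  h_med <- apply(sapply(members, function(m) m$model$h), 1L, stats::median)
  model <- structure(list(beta = beta_med,
                          bias = stats::setNames(bias_med, rownames(Z1)),
                          h = stats::setNames(h_med, rownames(Z1)),
                          alpha = members[[1L]]$model$alpha,
                          regressor_stats = members[[1L]]$model$regressor_stats),
                     class = "dynamical_model")
  list(Z = Z, model = model)
}
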