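#' Build the ODE-derived response/explanatory design
#'
#' The regression and mutual-information stages share a common design in
#' which each gene's rate of change is balanced against first-order decay.
#' For time-series data, a finite-difference response is formed for each
#' interval of `lag` sampling steps:
#' `y_i(t) = (x_i(t + L*dt) - x_i(t)) / (L*dt) + alpha * x_i(t)`,
#' paired with the time-lagged explanatory value `x_j(t)` at the left
#' endpoint.  For steady-state conditions the derivative vanishes and the
#' response is `y_i = alpha * x_i` paired with `x_j` in the same condition.
#' All columns are concatenated with a per-column kind tag.  For intervals
#' much longer than the decay time, the time-series response limits to the
#' steady-state form.
#'
#' @param ts List of time-series experiments (`time`, `values`), constant
#'   spacing within each experiment.
#' @param ss_blocks List of genes x conditions steady-state matrices
#'   (typically knock-out, knock-down and wild-type blocks).
#' @param tau_half Half-life parameter (default 50 time units).
#' @param lags Integer set of finite-difference lags, a subset of `{1, 2}`.
#'   Longer lags add smoothed-derivative observations; lags beyond 2 do not
#'   improve dynamic prediction on this design.
#' @param alpha_convention `"half_life"` sets `alpha = log(2) / tau_half`
#'   (first-order half-life formula, the default); `"time_constant"` sets
#'   `alpha = 1 / tau_half`.
#' @return A `response_design` list: `Y` (N x n_obs responses), `X`
#'   (N x n_obs explanatory values), `obs_kind` (`ts_lag1`, `ts_lag2` or
#'   `steady` per column), `alpha`, `tau_half`, `genes`.
#' @export
build_response_design <- function(ts, ss_blocks = list(), tau_half = 50,
                                  lags = c(1L, 2L),
                                  alpha_convention = c("half_life",
                                                       "time_constant")) {
  alpha_convention <- match.arg(alpha_convention)
  lags <- sort(unique(as.integer(lags)))
  if (!all(lags %in% c(1L, 2L))) {
    stop("lags must be a subset of {1, 2}", call. = FALSE)
  }
  alpha <- if (alpha_convention == "half_life") log(2) / tau_half else
    1 / tau_half
  Y_cols <- list(); X_cols <- list(); kind <- character(0)
  genes <- NULL
  for (exp in ts) {
    m <- exp$values
    if (is.null(genes)) genes <- rownames(m)
    tt <- exp$time
    dts <- diff(tt)
    if (length(tt) >= 2L &&
        max(abs(dts - dts[[1L]])) > 1e-9 * max(1, abs(dts[[1L]]))) {
      stop("non-constant time spacing in a time-series experiment",
           call. = FALSE)
    }
    delta <- dts[[1L]]
    T_pts <- ncol(m)
    for (L in lags) {
      if (T_pts <= L) next  # series too short for this lag
      idx <- seq_len(T_pts - L)
      y <- (m[, idx + L, drop = FALSE] - m[, idx, drop = FALSE]) /
        (L * delta) + alpha * m[, idx, drop = FALSE]
      Y_cols[[length(Y_cols) + 1L]] <- y
      X_cols[[length(X_cols) + 1L]] <- m[, idx, drop = FALSE]
      kind <- c(kind, rep(paste0("ts_lag", L), length(idx)))
    }
  }
  for (blk in ss_blocks) {
    if (is.null(blk) || ncol(blk) == 0L) next
    if (is.null(genes)) genes <- rownames(blk)
    Y_cols[[length(Y_cols) + 1L]] <- alpha * blk
    X_cols[[length(X_cols) + 1L]] <- blk
    kind <- c(kind, rep("steady", ncol(blk)))
  }
  if (!length(Y_cols)) stop("empty response design", call. = FALSE)
  Y <- do.call(cbind, Y_cols)
  X <- do.call(cbind, X_cols)
  colnames(Y) <- colnames(X) <- NULL
  rownames(Y) <- rownames(X) <- genes
  structure(list(Y = Y, X = X, obs_kind = kind, alpha = alpha,
                 tau_half = tau_half, genes = genes),
            class = "response_design")
}

#' Standardize explanatory rows to zero mean and unit variance
#'
#' Regulator profiles are standardized before model selection so that
#' regression coefficients are comparable across regulators.  Rows with
#' zero variance are flagged constant and left untouched; constant
#' regulators carry no information and are excluded from candidate lists.
#'
#' @param X Genes x observations explanatory matrix.
#' @return A list: `X_std` (standardized matrix), `stats` (data frame with
#'   per-gene `mean`, `sd`, `constant` flag).
#' @export
standardize_explanatory <- function(X) {
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  X_std <- X
  ok <- !constant
  X_std[ok, ] <- (X[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  list(X_std = X_std,
       stats = data.frame(gene = rownames(X), mean = mu, sd = sdv,
                          constant = constant, stringsAsFactors = FALSE,
                          row.names = NULL))
}
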