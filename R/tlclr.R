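# Equal-frequency discretization: stable rank (ties by original position)
# split evenly over n_bins bins.  Constant vectors return bin 0 as a marker
# that the variable carries no information.
quantile_bins <- function(x, n_bins) {
  if (length(unique(x)) <= 1L) return(rep(0L, length(x)))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

# MI in bits from two pre-binned integer vectors (0 = constant marker).
mi_from_bins <- function(bi, bj, n_bins) {
  if (bi[[1L]] == 0L || bj[[1L]] == 0L) return(0)
  n <- length(bi)
  joint <- tabulate((bi - 1L) * n_bins + bj, nbins = n_bins * n_bins) / n
  pj <- matrix(joint, n_bins, n_bins, byrow = TRUE)  # rows = bi, cols = bj
  pi_ <- rowSums(pj)
  pj_ <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pi_, pj_)[nz]))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Both variables are discretized into `n_bins` equal-frequency (quantile)
#' bins — ties resolved by stable rank then even splitting — and mutual
#' information is computed from the empirical joint distribution with a
#' base-2 logarithm (bits).  A constant vector has zero entropy, so its MI
#' with anything is 0 by definition.
#'
#' @param a,b Numeric vectors of equal length (>= `n_bins`).
#' @param n_bins Number of bins per variable (default 10).
#' @return MI estimate in bits (>= 0).
#' @export
mutual_information <- function(a, b, n_bins = 10L) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  mi_from_bins(quantile_bins(a, n_bins), quantile_bins(b, n_bins), n_bins)
}

#' Static mutual-information matrix
#'
#' MI between the raw expression profiles of every gene pair, treating
#' time-series and steady-state observations identically.  Symmetric by
#' construction; the diagonal is set to 0 as self-edges are excluded from
#' ranking.
#'
#' @param obs Genes x observations matrix (all conditions concatenated).
#' @param n_bins Bins per variable.
#' @return N x N symmetric MI matrix (bits) with zero diagonal.
#' @export
static_mi_matrix <- function(obs, n_bins = 10L) {
  n <- nrow(obs)
  bins <- t(apply(obs, 1L, quantile_bins, n_bins = n_bins))
  M <- matrix(0, n, n, dimnames = list(rownames(obs), rownames(obs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- mi_from_bins(bins[i, ], bins[j, ], n_bins)
    }
  }
  M
}

#' Dynamic mutual-information matrix
#'
#' MI between each gene's ODE-derived response profile and each candidate
#' regulator's time-lagged explanatory profile:
#' `M_dyn(i, j) = MI(y_i, x_j)`.  Because the response of i against the
#' lagged expression of j is not the same quantity as the response of j
#' against i, this matrix is generally asymmetric, which is what lets the
#' background correction assign a direction to an interaction.
#'
#' @param rd A [build_response_design()] object.
#' @param n_bins Bins per variable.
#' @return N x N (asymmetric) MI matrix in bits.
#' @export
dynamic_mi_matrix <- function(rd, n_bins = 10L) {
  n <- nrow(rd$Y)
  by <- t(apply(rd$Y, 1L, quantile_bins, n_bins = n_bins))
  bx <- t(apply(rd$X, 1L, quantile_bins, n_bins = n_bins))
  M <- matrix(0, n, n, dimnames = list(rd$genes, rd$genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- mi_from_bins(by[i, ], bx[j, ], n_bins)
    }
  }
  M
}

#' tlCLR background correction and directed confidence scores
#'
#' Each dynamic-MI value is placed in the context of two background
#' distributions and converted to positive z-scores (negative z-scores are
#' set to zero): `z1(i, j)` standardizes `M_dyn(i, j)` against row i of the
#' dynamic-MI matrix, and `z2(i, j)` standardizes it against column j of
#' the static-MI matrix.  The final directed confidence combines the two by
#' root-sum-square: `Z(i, j) = sqrt(z1^2 + z2^2)`, with zero diagonal.
#' Because of the clipping, the resulting matrix is somewhat sparse.
#'
#' @param M_dyn Dynamic MI matrix from [dynamic_mi_matrix()].
#' @param M_stat Static MI matrix from [static_mi_matrix()] on the same
#'   data.
#' @return N x N confidence matrix (rows targets, columns regulators).
#' @export
tlclr_scores <- function(M_dyn, M_stat) {
  n <- nrow(M_dyn)
  stopifnot(ncol(M_dyn) == n, all(dim(M_stat) == c(n, n)))
  row_mu <- rowMeans(M_dyn)
  row_sd <- apply(M_dyn, 1L, stats::sd)
  col_mu <- colMeans(M_stat)
  col_sd <- apply(M_stat, 2L, stats::sd)
  z1 <- (M_dyn - row_mu) / ifelse(row_sd > 0, row_sd, Inf)
  z2 <- sweep(sweep(M_dyn, 2L, col_mu), 2L,
              ifelse(col_sd > 0, col_sd, Inf), "/")
  z1 <- pmax(z1, 0)
  z2 <- pmax(z2, 0)
  Z <- sqrt(z1^2 + z2^2)
  diag(Z) <- 0
  dimnames(Z) <- dimnames(M_dyn)
  Z
}
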