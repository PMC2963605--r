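#' Median-corrected wild-type estimate
#'
#' Any single wild-type profile is a noisy estimate of population wild-type
#' expression.  Because regulatory networks are sparse, most genes are
#' unaffected in most single knock-outs, so the knock-out block provides
#' many additional quasi-wild-type observations.  The corrected estimate of
#' each gene's wild-type level is therefore the median of its expression
#' over the concatenated wild-type and knock-out columns; the per-gene
#' noise scale is the sample standard deviation over the same columns.
#'
#' @param X_wt Genes x wild-type-conditions matrix (series starts plus the
#'   provided wild-type profile; 11 columns in the DREAM4 design).
#' @param X_ko Genes x knock-out-conditions matrix.
#' @param include_self_ko Keep gene i's own knock-out column when computing
#'   its median/sd (default `TRUE`).  The self column is guaranteed
#'   non-wild-type, so excluding it is offered as an option.
#' @return A `wildtype_estimate` list: `median`, `sd` (sample sd, ddof 1),
#'   `n_obs`.
#' @export
corrected_wildtype <- function(X_wt, X_ko, include_self_ko = TRUE) {
  stopifnot(nrow(X_wt) == nrow(X_ko))
  n <- nrow(X_wt)
  all_cols <- cbind(X_wt, X_ko)
  if (ncol(all_cols) < 2L) {
    stop("need at least 2 wild-type + knock-out columns to estimate sd",
         call. = FALSE)
  }
  if (include_self_ko) {
    med <- apply(all_cols, 1L, stats::median)
    sdv <- apply(all_cols, 1L, stats::sd)
  } else {
    med <- sdv <- numeric(n)
    for (i in seq_len(n)) {
      vals <- c(X_wt[i, ], X_ko[i, -i])
      med[[i]] <- stats::median(vals)
      sdv[[i]] <- stats::sd(vals)
    }
  }
  structure(list(median = stats::setNames(med, rownames(X_wt)),
                 sd = stats::setNames(sdv, rownames(X_wt)),
                 n_obs = ncol(all_cols)),
            class = "wildtype_estimate")
}

#' Median-corrected z-score (MCZ) confidence matrix
#'
#' The confidence that regulator j regulates target i is the absolute
#' deviation of i's expression under j's knock-out from i's median-corrected
#' wild-type level, in units of i's wild-type-and-knock-out standard
#' deviation: `Z(i, j) = |x_i^{KO j} - median_i| / sd_i`.
#'
#' Genes with zero standard deviation score 0 where the deviation is also
#' zero, and otherwise receive the maximum finite score in the matrix plus
#' one — a large sentinel that preserves the ranking without infinities.
#'
#' @param X_ko Genes x knock-out-conditions matrix.
#' @param komap Named integer vector mapping each gene id to its knock-out
#'   column.
#' @param est A [corrected_wildtype()] estimate computed on the same data.
#' @return N x N `confidence matrix` (rows targets, columns regulators,
#'   diagonal 0) with gene ids as dimnames.
#' @export
mcz_scores <- function(X_ko, komap, est) {
  genes <- rownames(X_ko)
  n <- nrow(X_ko)
  if (!all(genes %in% names(komap))) {
    stop("knock-out map is missing genes present in the expression matrix",
         call. = FALSE)
  }
  Z <- matrix(0, n, n, dimnames = list(genes, genes))
  sd_ok <- est$sd > 0
  for (j in seq_len(n)) {
    col <- X_ko[, komap[[genes[[j]]]]]
    dev <- abs(col - est$median)
    z <- numeric(n)
    z[sd_ok] <- dev[sd_ok] / est$sd[sd_ok]
    z[!sd_ok & dev > 0] <- NA  # sentinel filled in below
    Z[, j] <- z
  }
  diag(Z) <- 0
  if (anyNA(Z)) {
    sentinel <- max(Z[!is.na(Z)]) + 1
    Z[is.na(Z)] <- sentinel
  }
  Z
}

#' Percentile filter mask on MCZ scores
#'
#' Before combining MCZ with other rankings, interactions whose MCZ score
#' falls in the lower `lower_percentile` percent of all off-diagonal scores
#' are removed.  Entries pass only if strictly above the percentile value;
#' with `lower_percentile = 0` every off-diagonal entry passes.
#'
#' @param Z_mcz MCZ confidence matrix.
#' @param lower_percentile Percentile in `[0, 100)`.
#' @return Logical N x N mask, `TRUE` where the interaction is kept;
#'   diagonal always `FALSE`.
#' @export
mcz_filter_mask <- function(Z_mcz, lower_percentile = 20) {
  stopifnot(lower_percentile >= 0, lower_percentile < 100)
  n <- nrow(Z_mcz)
  off <- offdiag_mask(n)
  mask <- matrix(FALSE, n, n, dimnames = dimnames(Z_mcz))
  if (lower_percentile == 0) {
    mask[off] <- TRUE
    return(mask)
  }
  cut <- stats::quantile(Z_mcz[off], lower_percentile / 100, names = FALSE)
  mask[off] <- Z_mcz[off] > cut
  mask
}
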