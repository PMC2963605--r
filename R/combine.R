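#' Rank-transplant combination of two confidence matrices
#'
#' Confidence scores from different methods live on incompatible scales, so
#' before combining, the ranking of `B` is re-expressed on `A`'s value
#' scale: the highest-ranking nonzero entry of `B` receives the value of
#' `A`'s highest-ranking entry, the second receives `A`'s second value,
#' and so on until every nonzero entry of `B` has been replaced.  If `B`
#' has more nonzero entries than `A` has positive values, the remainder
#' receive `A`'s smallest positive value.  The combined matrix is the
#' element-wise sum `A + B'` (sum and mean give identical rankings), with
#' zero diagonal.
#'
#' @param A Reference confidence matrix (provides the value scale).
#' @param B Confidence matrix whose ranks are transplanted onto `A`'s
#'   scale.
#' @return Combined N x N confidence matrix.
#' @export
rank_transplant_combine <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  n <- nrow(A)
  off <- which(offdiag_mask(n))
  a_vals <- sort(A[off], decreasing = TRUE)
  a_pos <- a_vals[a_vals > 0]
  Bp <- matrix(0, n, n, dimnames = dimnames(B))
  b_off <- B[off]
  nz <- which(b_off > 0)
  if (length(nz) && length(a_pos)) {
    ord <- nz[order(-b_off[nz], nz)]      # deterministic tie order
    k <- pmin(seq_along(ord), length(a_pos))  # overflow -> smallest positive
    Bp[off[ord]] <- a_pos[k]
  }
  out <- A + Bp
  diag(out) <- 0
  dimnames(out) <- dimnames(A)
  out
}

#' Pipeline 2: combine tlCLR and Inferelator confidence matrices
#'
#' The Inferelator ranking is transplanted onto the tlCLR value scale and
#' the two are summed element-wise.
#'
#' @param Z_tlclr tlCLR confidence matrix (reference scale).
#' @param Z_inf Inferelator confidence matrix.
#' @return Combined confidence matrix.
#' @export
pipeline2_combine <- function(Z_tlclr, Z_inf) {
  rank_transplant_combine(Z_tlclr, Z_inf)
}

#' Pipeline 3: combine the pipeline-2 matrix with MCZ
#'
#' Scores of equal rank from the MCZ matrix are transplanted into the
#' pipeline-2 ranking (MCZ provides the reference scale) and summed.
#'
#' @param Z_p2 Pipeline-2 combined confidence matrix.
#' @param Z_mcz MCZ confidence matrix (reference scale).
#' @return Combined confidence matrix.
#' @export
pipeline3_combine <- function(Z_p2, Z_mcz) {
  rank_transplant_combine(Z_mcz, Z_p2)
}
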