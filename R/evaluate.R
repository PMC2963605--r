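# Encode directed pairs as integers and lay out the full universe of
# P = N(N-1) non-self pairs in the package's deterministic tie order
# (regulator index, then target index).  Edges absent from a ranked list
# are appended in this order with score 0.
full_ranking_codes <- function(ranked, gold) {
  genes <- gold$genes
  n <- length(genes)
  ri <- match(ranked$regulator, genes)
  ti <- match(ranked$target, genes)
  if (anyNA(ri) || anyNA(ti)) {
    stop("ranked list mentions genes outside the gold-standard universe",
         call. = FALSE)
  }
  code <- (ri - 1L) * n + ti
  if (anyDuplicated(code)) {
    stop("ranked list contains duplicate edges", call. = FALSE)
  }
  reg_all <- rep(seq_len(n), each = n)
  tgt_all <- rep(seq_len(n), times = n)
  keep <- reg_all != tgt_all
  all_codes <- (reg_all[keep] - 1L) * n + tgt_all[keep]
  c(code, setdiff(all_codes, code))
}

#' Area under the precision-recall curve of a ranked edge list
#'
#' Precision-recall points are accumulated edge by edge down the ranked
#' list and the area is the step-wise sum of precision times recall
#' increment (no interpolation), the convention of the DREAM scorer.  A
#' ranking that places every true edge above every non-edge scores exactly
#' 1; a random ranking of a sparse gold standard scores close to the edge
#' density.
#'
#' @param ranked Data frame (`regulator`, `target`, `score`) sorted by
#'   non-increasing score, covering a prefix or all of the edge universe;
#'   unlisted edges are appended in deterministic tie order with score 0.
#' @param gold A [gold_standard()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(ranked, gold) {
  n_true <- nrow(gold$edges)
  if (n_true == 0L) stop("gold standard has no edges", call. = FALSE)
  code_full <- full_ranking_codes(ranked, gold)
  n <- length(gold$genes)
  gold_code <- (match(gold$edges$regulator, gold$genes) - 1L) * n +
    match(gold$edges$target, gold$genes)
  is_true <- code_full %in% gold_code
  tp <- cumsum(is_true)
  prec <- tp / seq_along(code_full)
  # recall increments by 1/n_true exactly at true edges
  sum(prec[is_true]) / n_true
}

#' Relative rank of every gold-standard edge
#'
#' The relative rank of a true edge is its 1-based position in the full
#' ranking divided by `P = N(N-1)`, the number of possible directed
#' non-self pairs; it is used as a per-edge error measure (small is good).
#'
#' @inheritParams aupr
#' @return Named numeric vector in `(0, 1]`, one value per gold edge
#'   (names `regulator->target`).
#' @export
relative_ranks <- function(ranked, gold) {
  code_full <- full_ranking_codes(ranked, gold)
  n <- length(gold$genes)
  gold_code <- (match(gold$edges$regulator, gold$genes) - 1L) * n +
    match(gold$edges$target, gold$genes)
  pos <- match(gold_code, code_full)
  stats::setNames(pos / gold$universe,
                  paste0(gold$edges$regulator, "->", gold$edges$target))
}

#' Prediction error binned by regulator expression
#'
#' Regulators are summarized by the median of their expression across all
#' knock-out conditions and split into `n_bins` equal-count bins; each gold
#' edge's relative rank is assigned to its regulator's bin.  Methods that
#' rely on knock-out deviations make larger errors for weakly expressed
#' regulators, which this view makes visible.
#'
#' @inheritParams aupr
#' @param X_ko Genes x knock-out-conditions expression matrix.
#' @param komap Named knock-out map (present for interface symmetry;
#'   binning uses all columns of `X_ko`).
#' @param n_bins Number of equal-count bins (default 7).
#' @return A list with `bins` (per-bin list of relative-rank vectors,
#'   ordered low to high regulator expression) and `regulator_bins`
#'   (data frame `regulator`, `median_expression`, `bin`).
#' @export
binned_error_by_regulator_expression <- function(ranked, gold, X_ko, komap,
                                                 n_bins = 7L) {
  rr <- relative_ranks(ranked, gold)
  regs <- sort(unique(gold$edges$regulator))
  med <- apply(X_ko[regs, , drop = FALSE], 1L, stats::median)
  # equal-count binning by rank (stable on ties)
  bin <- as.integer(ceiling(rank(med, ties.method = "first") *
                              n_bins / length(regs)))
  names(bin) <- regs
  bins <- lapply(seq_len(n_bins), function(b) {
    rr[gold$edges$regulator %in% regs[bin == b]]
  })
  list(bins = bins,
       regulator_bins = data.frame(regulator = regs,
                                   median_expression = unname(med),
                                   bin = unname(bin),
                                   stringsAsFactors = FALSE))
}
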