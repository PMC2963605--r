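#' Read a DREAM4-style steady-state expression table
#'
#' Steady-state tables are tab-delimited: the first row holds gene ids and
#' every subsequent row is one condition (one knock-out, knock-down or
#' wild-type profile).  The table is transposed on read so that genes are
#' rows and conditions are columns, the orientation used throughout the
#' package.
#'
#' @param path Path to a tab-delimited text file.
#' @param knockout_semantics If `TRUE`, row `k` of the file is interpreted as
#'   the steady state in which gene `k`'s transcription rate was zeroed (or
#'   halved, for knock-down tables), and a knock-out map is returned
#'   alongside the matrix.
#' @return If `knockout_semantics` is `FALSE`, a genes x conditions numeric
#'   matrix with gene ids as row names.  Otherwise a list with elements
#'   `expr` (the matrix) and `komap` (named integer vector mapping each gene
#'   id to its perturbation column).
#' @export
read_steady_state_table <- function(path, knockout_semantics = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("steady-state table needs a header and at least one condition row",
         call. = FALSE)
  }
  genes <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in header", call. = FALSE)
  n <- length(genes)
  rows <- lapply(seq_along(lines)[-1L], function(k) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n) {
      stop(sprintf("line %d has %d fields, expected %d", k, length(fields), n),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric value on line %d", k), call. = FALSE)
    }
    vals
  })
  expr <- t(do.call(rbind, rows))
  rownames(expr) <- genes
  n_cond <- ncol(expr)
  if (knockout_semantics) {
    if (n_cond != n) {
      stop(sprintf(
        "knock-out table must have one row per gene (%d rows for %d genes)",
        n_cond, n), call. = FALSE)
    }
    colnames(expr) <- paste0("KO_", genes)
    komap <- stats::setNames(seq_len(n), genes)
    list(expr = expr, komap = komap)
  } else {
    colnames(expr) <- paste0("C", seq_len(n_cond))
    expr
  }
}

#' Read a DREAM4-style time-series table
#'
#' The file's first column is headed `Time`; remaining columns are gene ids.
#' Consecutive rows with increasing times belong to one experiment; a drop
#' in the time value starts a new experiment.  Within an experiment the
#' sampling interval must be constant.
#'
#' @param path Path to a tab-delimited text file.
#' @return A list of experiments, each a list with `time` (numeric vector)
#'   and `values` (genes x timepoints matrix).
#' @export
read_time_series_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[[1L]] != "Time") {
    stop("time-series table must start with a 'Time' column", call. = FALSE)
  }
  genes <- header[-1L]
  n <- length(genes)
  times <- numeric(0)
  vals <- list()
  for (k in seq_along(lines)[-1L]) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != n + 1L) {
      stop(sprintf("line %d has %d fields, expected %d", k, length(fields),
                   n + 1L), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num))) {
      stop(sprintf("non-numeric value on line %d", k), call. = FALSE)
    }
    times <- c(times, num[[1L]])
    vals[[length(vals) + 1L]] <- num[-1L]
  }
  # split on time resets
  brk <- c(1L, which(diff(times) <= 0) + 1L)
  ends <- c(brk[-1L] - 1L, length(times))
  experiments <- vector("list", length(brk))
  for (e in seq_along(brk)) {
    idx <- brk[[e]]:ends[[e]]
    tt <- times[idx]
    if (length(tt) < 2L) {
      stop("each time-series experiment needs at least 2 time points",
           call. = FALSE)
    }
    dts <- diff(tt)
    if (max(abs(dts - dts[[1L]])) > 1e-9 * max(1, abs(dts[[1L]]))) {
      stop("non-constant time spacing within a time-series experiment",
           call. = FALSE)
    }
    m <- do.call(cbind, vals[idx])
    rownames(m) <- genes
    experiments[[e]] <- list(time = tt, values = m)
  }
  experiments
}

#' Turn a confidence matrix into a deterministically ranked edge list
#'
#' Entry `(i, j)` of a confidence matrix is the confidence that regulator
#' `j` regulates target `i`; the diagonal (self-regulation) is excluded.
#' Edges are sorted by score descending with ties broken lexicographically
#' by (regulator index, target index) so the ordering is deterministic.
#'
#' @param Z N x N confidence matrix (rows targets, columns regulators) with
#'   gene ids as dimnames (defaults to `G1..GN`).
#' @param max_edges Optional cap on the number of edges returned.
#' @return A data frame with columns `regulator`, `target`, `score`, ordered
#'   by non-increasing score.
#' @export
ranked_edges <- function(Z, max_edges = Inf) {
  stopifnot_finite_matrix(Z, "confidence matrix")
  n <- nrow(Z)
  if (ncol(Z) != n) stop("confidence matrix must be square", call. = FALSE)
  genes <- rownames(Z)
  if (is.null(genes)) genes <- gene_labels(n)
  tgt <- rep(seq_len(n), times = n)   # row index
  reg <- rep(seq_len(n), each = n)    # column index
  keep <- tgt != reg
  tgt <- tgt[keep]; reg <- reg[keep]
  score <- Z[cbind(tgt, reg)]
  ord <- order(-score, reg, tgt)
  out <- data.frame(regulator = genes[reg[ord]],
                    target = genes[tgt[ord]],
                    score = score[ord],
                    stringsAsFactors = FALSE)
  if (is.finite(max_edges) && nrow(out) > max_edges) {
    out <- out[seq_len(max_edges), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a ranked edge list to a DREAM4-style prediction file
#'
#' Lines have the form `regulator<TAB>target<TAB>score`.
#'
#' @inheritParams ranked_edges
#' @param path Output file path.
#' @return Invisibly, the ranked edge data frame that was written.
#' @export
write_ranked_edges <- function(Z, path, max_edges = Inf) {
  edges <- ranked_edges(Z, max_edges)
  writeLines(sprintf("%s\t%s\t%.10g", edges$regulator, edges$target,
                     edges$score), path)
  invisible(edges)
}

#' Read a ranked edge prediction file
#'
#' @param path Path to a three-column tab-delimited file
#'   (regulator, target, score).
#' @return Data frame with columns `regulator`, `target`, `score`.
#' @export
read_ranked_edges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("regulator", "target", "score"),
                          colClasses = c("character", "character", "numeric"))
  df
}

#' Read a gold-standard edge file
#'
#' Gold standards are three-column tab-delimited files
#' `regulator<TAB>target<TAB>flag` with flag 1 for a true edge and 0 for a
#' verified non-edge; absent pairs are non-edges.
#'
#' @param path Path to the gold-standard file.
#' @param genes Optional character vector of all gene ids in the network.
#'   If omitted, the gene universe is inferred from the labels present
#'   (using the numeric suffix of `G<k>`-style labels when available).
#' @return A list with `edges` (data frame `regulator`, `target`), `genes`,
#'   and `universe` (the count `P = N(N-1)` of possible directed non-self
#'   pairs).
#' @export
read_gold_standard <- function(path, genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  reg <- character(0); tgt <- character(0); flag <- integer(0)
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L) {
      stop(sprintf("line %d: expected 3 tab-separated fields", k),
           call. = FALSE)
    }
    f <- fields[[3L]]
    if (!f %in% c("0", "1")) {
      stop(sprintf("line %d: edge flag must be 0 or 1, got '%s'", k, f),
           call. = FALSE)
    }
    reg <- c(reg, fields[[1L]]); tgt <- c(tgt, fields[[2L]])
    flag <- c(flag, as.integer(f))
  }
  seen <- unique(c(reg, tgt))
  if (is.null(genes)) {
    if (all(grepl("^G[0-9]+$", seen))) {
      genes <- gene_labels(max(as.integer(sub("^G", "", seen))))
    } else {
      genes <- sort(seen)
    }
  }
  if (!all(seen %in% genes)) {
    stop("gold standard mentions genes outside the declared universe",
         call. = FALSE)
  }
  keep <- flag == 1L
  edges <- data.frame(regulator = reg[keep], target = tgt[keep],
                      stringsAsFactors = FALSE)
  if (any(edges$regulator == edges$target)) {
    stop("gold standard contains a self-edge", call. = FALSE)
  }
  edges <- unique(edges)
  n <- length(genes)
  gold_standard(edges, genes)
}

#' Construct a gold standard from an edge data frame
#'
#' @param edges Data frame with columns `regulator` and `target`.
#' @param genes Character vector of all gene ids.
#' @return Gold-standard list (`edges`, `genes`, `universe`).
#' @export
gold_standard <- function(edges, genes) {
  n <- length(genes)
  stopifnot(all(edges$regulator %in% genes), all(edges$target %in% genes),
            !any(edges$regulator == edges$target))
  structure(list(edges = edges, genes = genes, universe = n * (n - 1L)),
            class = "gold_standard")
}

#' Write a steady-state expression matrix in the DREAM4 dialect
#'
#' @param expr Genes x conditions matrix with gene ids as row names.
#' @param path Output file path.
#' @export
write_steady_state_table <- function(expr, path) {
  genes <- rownames(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(genes, collapse = "\t"), con)
  for (k in seq_len(ncol(expr))) {
    writeLines(paste(format(expr[, k], digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a time-series set in the DREAM4 dialect
#'
#' @param ts List of experiments as returned by [read_time_series_table()].
#' @param path Output file path.
#' @export
write_time_series_table <- function(ts, path) {
  genes <- rownames(ts[[1L]]$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Time", genes), collapse = "\t"), con)
  for (exp in ts) {
    for (k in seq_along(exp$time)) {
      writeLines(paste(format(c(exp$time[[k]], exp$values[, k]), digits = 15,
                              trim = TRUE, scientific = FALSE),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a gold standard to a three-column edge file
#'
#' Only true edges are written (flag 1); absent pairs are non-edges.
#'
#' @param gold Gold standard as returned by [gold_standard()].
#' @param path Output file path.
#' @export
write_gold_standard <- function(gold, path) {
  writeLines(sprintf("%s\t%s\t1", gold$edges$regulator, gold$edges$target),
             path)
  invisible(path)
}
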