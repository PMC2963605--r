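#' Simulate a noise-free dataset from a linear regulatory ODE
#'
#' Validation generator for the regression stages: dynamics are the linear
#' model `dx/dt = b + W x - alpha x`, the same functional form the
#' Inferelator-style regression assumes.  Time series follow the explicit
#' Euler map `x(t + dt) = x(t) + dt * (b + W x(t) - alpha x(t))`, so the
#' lag-1 finite-difference response satisfies `y = W x + b` exactly, and
#' steady states solve `alpha x = W x + b` exactly.  This makes parameter
#' recovery checkable to numerical precision; it is synthetic validation
#' data, not a realistic expression simulator (see
#' [simulate_dream4_dataset()] for that).
#'
#' Weights are scaled relative to the degradation rate so the Euler map is
#' stable and the steady-state system is diagonally dominant.
#'
#' @param n_genes Number of genes.
#' @param mean_in_degree Expected regulators per gene.
#' @param n_series Number of time series.
#' @param n_points Points per series.
#' @param dt Sampling interval.
#' @param tau_half Half-life defining `alpha = log(2) / tau_half`.
#' @param n_double_ko Number of double knock-out pairs with exact truth.
#' @param seed Integer seed.
#' @return A list with `net` (`adjacency`, `basal`, `decay`, `genes`),
#'   `ts`, `wt`, `ko` (`expr` + `komap`), `kd`, `double_ko`
#'   (`pairs` + `truth`), `gold` — the same shape as a `dream4_dataset`.
#' @export
simulate_linear_dataset <- function(n_genes = 8L, mean_in_degree = 1.5,
                                    n_series = 4L, n_points = 11L, dt = 50,
                                    tau_half = 50, n_double_ko = 5L,
                                    seed = 1L) {
  alpha <- log(2) / tau_half
  genes <- gene_labels(n_genes)
  with_seed(seed, {
    n <- n_genes
    p_edge <- mean_in_degree / (n - 1)
    W <- matrix(0, n, n)
    cand <- which(offdiag_mask(n))
    hit <- cand[stats::runif(length(cand)) < p_edge]
    if (length(hit)) {
      u <- stats::runif(length(hit), 0.1, 0.4) *
        ifelse(stats::runif(length(hit)) < 0.7, 1, -1)
      W[hit] <- u * alpha  # weights in units of the degradation rate
    }
    b <- alpha * stats::runif(n, 0.5, 2)

    lin_ss <- function(ko = integer(0)) {
      Wm <- W; bm <- b
      if (length(ko)) { Wm[ko, ] <- 0; bm[ko] <- 0 }
      solve(diag(alpha, n) - Wm, bm)
    }
    x_wt <- lin_ss()

    euler_series <- function(x0, Wm = W, bm = b) {
      out <- matrix(0, n, n_points, dimnames = list(genes, NULL))
      x <- x0
      for (k in seq_len(n_points)) {
        out[, k] <- x
        x <- x + dt * (bm + drop(Wm %*% x) - alpha * x)
      }
      out
    }

    ts <- lapply(seq_len(n_series), function(s) {
      # start from a randomly perturbed state and relax under the true model
      x0 <- x_wt * exp(stats::rnorm(n, 0, 0.3))
      list(time = seq(0, by = dt, length.out = n_points),
           values = euler_series(x0))
    })

    ko_true <- sapply(seq_len(n), function(g) lin_ss(g))
    kd_true <- sapply(seq_len(n), function(g) {
      Wm <- W; bm <- b
      Wm[g, ] <- 0.5 * Wm[g, ]; bm[g] <- 0.5 * bm[g]
      solve(diag(alpha, n) - Wm, bm)
    })
    dimnames(ko_true) <- list(genes, paste0("KO_", genes))
    dimnames(kd_true) <- list(genes, paste0("KD_", genes))
    komap <- stats::setNames(seq_len(n), genes)

    pair_idx <- which(upper.tri(matrix(0, n, n)))
    chosen <- sample(pair_idx, min(n_double_ko, length(pair_idx)))
    p <- row(matrix(0, n, n))[chosen]
    q <- col(matrix(0, n, n))[chosen]
    truth <- sapply(seq_along(chosen), function(k) lin_ss(c(p[[k]], q[[k]])))
    dimnames(truth) <- list(genes, paste0("DKO", seq_along(chosen)))
    pairs <- data.frame(gene_a = genes[p], gene_b = genes[q],
                        stringsAsFactors = FALSE)

    # series start from perturbed (non-steady) states, so the wild-type
    # block is the exact steady state alone
    wt <- matrix(x_wt, ncol = 1, dimnames = list(genes, "WT1"))
    nz <- which(W != 0, arr.ind = TRUE)
    gold <- gold_standard(
      data.frame(regulator = genes[nz[, "col"]], target = genes[nz[, "row"]],
                 stringsAsFactors = FALSE), genes)
    net <- list(n_genes = n, adjacency = W, basal = b, decay = alpha,
                genes = genes, seed = as.integer(seed))
    structure(list(ts = ts, wt = wt,
                   ko = list(expr = ko_true, komap = komap),
                   kd = list(expr = kd_true, komap = komap),
                   double_ko = list(pairs = pairs, truth = truth),
                   gold = gold, wt_true = x_wt, net = net,
                   config = NULL),
              class = "dream4_dataset")
  })
}
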