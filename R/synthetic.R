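#' Generate a sparse signed regulatory topology
#'
#' Candidate directed pairs (no self-loops) receive an edge independently
#' with probability `mean_in_degree / (n_genes - 1)`, so the expected
#' in-degree of every gene is `mean_in_degree`.  Edge weights are drawn
#' uniformly in magnitude and signed positive (activation) with probability
#' `activating_fraction`.  Basal transcription rates are scaled so that
#' unregulated wild-type expression is order one and heterogeneous across
#' genes, mimicking the spread of expression levels in microarray
#' compendia.
#'
#' @param n_genes Number of genes (>= 2).
#' @param mean_in_degree Expected number of regulators per gene (default 2).
#' @param seed Integer seed; the same seed reproduces the same network.
#' @param activating_fraction Probability that an edge is activating.
#' @param w_range Magnitude range for edge weights on the sigmoid input
#'   scale.
#' @param tau_half mRNA half-life in simulation time units; the common
#'   degradation rate is `log(2) / tau_half`.
#' @return A `synthetic_network` list: `n_genes`, `adjacency` (N x N signed
#'   weights, entry (i, j) = effect of regulator j on target i), `basal`
#'   (transcription rates), `input_bias`, `decay`, `genes`, `seed`.
#' @export
generate_topology <- function(n_genes, mean_in_degree = 2, seed = 1L,
                              activating_fraction = 0.7,
                              w_range = c(0.5, 2), tau_half = 50) {
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  if (mean_in_degree >= n_genes - 1L) {
    stop("mean_in_degree must be smaller than n_genes - 1", call. = FALSE)
  }
  alpha <- log(2) / tau_half
  with_seed(seed, {
    n <- n_genes
    p_edge <- mean_in_degree / (n - 1)
    W <- matrix(0, n, n)
    cand <- which(offdiag_mask(n))
    hit <- cand[stats::runif(length(cand)) < p_edge]
    if (length(hit)) {
      mag <- stats::runif(length(hit), w_range[[1L]], w_range[[2L]])
      sgn <- ifelse(stats::runif(length(hit)) < activating_fraction, 1, -1)
      W[hit] <- mag * sgn
    }
    # basal rate = decay * target-scale expression, log-uniform in [0.25, 4]
    scale <- exp(stats::runif(n, log(0.25), log(4)))
    structure(list(
      n_genes = n,
      adjacency = W,
      basal = alpha * scale,
      input_bias = stats::rnorm(n, 0, 1),
      decay = alpha,
      genes = gene_labels(n),
      seed = as.integer(seed)
    ), class = "synthetic_network")
  })
}

#' Simulation configuration for the in-silico benchmark generator
#'
#' Defaults emulate the DREAM4 100-gene design: 10 perturbation/relaxation
#' time series, measurements every 50 time units, per-gene knock-out and
#' half-rate knock-down steady states, expression-proportional measurement
#' noise, and 20 double knock-out pairs per network.
#'
#' @param n_series Number of perturbation time series (each contributes a
#'   perturbation phase and a relaxation phase, stored as two experiments).
#' @param points_per_phase Measurements per phase.
#' @param dt Sampling interval (arbitrary time units).
#' @param noise_coeff Multiplicative noise coefficient `c` in
#'   `x <- max(0, x * (1 + c * eps) + noise_floor * eps')`.
#' @param noise_floor Additive noise floor.
#' @param kd_factor Knock-down transcription factor (fraction of wild-type
#'   rate, default 0.5).
#' @param n_double_ko Number of double knock-out pairs with held-out truth.
#' @param perturb_fraction Fraction of genes whose basal rate is shifted in
#'   each perturbation phase.
#' @param perturb_range Log-uniform range of multiplicative basal-rate
#'   shifts.
#' @param seed Integer seed.
#' @return A `sim_config` list of the above.
#' @export
sim_config <- function(n_series = 10L, points_per_phase = 11L, dt = 50,
                       noise_coeff = 0.1, noise_floor = 0.01,
                       kd_factor = 0.5, n_double_ko = 20L,
                       perturb_fraction = 1 / 3,
                       perturb_range = c(0.25, 4), seed = 1L) {
  stopifnot(dt > 0, noise_coeff >= 0, kd_factor > 0, kd_factor < 1,
            points_per_phase >= 2L)
  structure(list(n_series = as.integer(n_series),
                 points_per_phase = as.integer(points_per_phase), dt = dt,
                 noise_coeff = noise_coeff, noise_floor = noise_floor,
                 kd_factor = kd_factor, n_double_ko = as.integer(n_double_ko),
                 perturb_fraction = perturb_fraction,
                 perturb_range = perturb_range, seed = as.integer(seed)),
            class = "sim_config")
}

# Production term of the regulatory ODE: m * sigmoid(W x + b).
production_rate <- function(net, x, basal = net$basal) {
  basal * stats::plogis(drop(net$adjacency %*% x) + net$input_bias)
}

#' Steady-state expression of a synthetic network under perturbations
#'
#' Dynamics are `dx_i/dt = m_i * sigma(sum_j w_ij x_j + b_i) - alpha x_i`
#' with a logistic production sigmoid.  Knock-out sets `m_i = 0`,
#' knock-down multiplies `m_i` by `kd_factor`.  The fixed point is found by
#' damped fixed-point iteration, falling back to numerical integration
#' (lsoda) followed by a second polish; convergence is certified by
#' `max |dx/dt| < tol`.
#'
#' @param net A `synthetic_network`.
#' @param ko_genes Character vector of knocked-out gene ids.
#' @param kd_genes Character vector of knocked-down gene ids.
#' @param kd_factor Knock-down transcription factor.
#' @param basal_override Optional replacement basal-rate vector (used for
#'   perturbation phases).
#' @param x_init Optional starting state for the solver.
#' @param tol Residual tolerance on `max |dx/dt|`.
#' @return Named nonnegative expression vector; knocked-out genes are
#'   exactly 0.
#' @export
simulate_steady_state <- function(net, ko_genes = character(0),
                                  kd_genes = character(0), kd_factor = 0.5,
                                  basal_override = NULL, x_init = NULL,
                                  tol = 1e-9) {
  m <- if (is.null(basal_override)) net$basal else basal_override
  idx_ko <- match(ko_genes, net$genes)
  idx_kd <- match(kd_genes, net$genes)
  if (any(is.na(idx_ko)) || any(is.na(idx_kd))) {
    stop("unknown gene id in ko_genes/kd_genes", call. = FALSE)
  }
  m[idx_ko] <- 0
  m[idx_kd] <- kd_factor * m[idx_kd]
  alpha <- net$decay
  x <- if (is.null(x_init)) m * stats::plogis(net$input_bias) / alpha else x_init
  polish <- function(x, gamma = 0.3, maxit = 20000L) {
    for (it in seq_len(maxit)) {
      g <- production_rate(net, x, m) / alpha
      r <- max(abs(alpha * (g - x)))
      if (r < tol) return(list(x = x, ok = TRUE))
      x <- (1 - gamma) * x + gamma * g
    }
    list(x = x, ok = FALSE)
  }
  res <- polish(x)
  if (!res$ok) {
    deriv <- function(t, x, parms) {
      list(production_rate(net, x, m) - alpha * x)
    }
    sol <- deSolve::ode(y = res$x, times = c(0, 20 / alpha), func = deriv,
                        parms = NULL)
    res <- polish(sol[nrow(sol), -1L], gamma = 0.1)
    if (!res$ok) {
      stop(sprintf(
        "steady state did not converge (ko: %s; kd: %s)",
        paste(ko_genes, collapse = ","), paste(kd_genes, collapse = ",")),
        call. = FALSE)
    }
  }
  x <- pmax(res$x, 0)
  x[idx_ko] <- 0
  stats::setNames(as.numeric(x), net$genes)
}

# Integrate the network ODE over an evenly spaced grid; returns genes x
# timepoints matrix (column 1 is the initial state).
integrate_phase <- function(net, x0, n_points, dt, basal = net$basal) {
  deriv <- function(t, x, parms) {
    list(production_rate(net, x, basal) - net$decay * x)
  }
  times <- seq(0, by = dt, length.out = n_points)
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv,
                      parms = NULL)
  m <- t(unname(sol[, -1L, drop = FALSE]))
  rownames(m) <- net$genes
  m
}

# Expression-proportional observational noise, truncated at zero.
apply_noise <- function(x, coeff, floor) {
  if (coeff == 0 && floor == 0) return(x)
  eps <- stats::rnorm(length(x))
  eps2 <- stats::rnorm(length(x))
  out <- pmax(0, x * (1 + coeff * eps) + floor * eps2)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Simulate a complete DREAM4-style benchmark dataset
#'
#' Produces everything a network-inference pipeline consumes: perturbation
#' and relaxation time series (stored as separate experiments), a wild-type
#' block made of the first observation of each series plus one provided
#' wild-type profile, per-gene knock-out and knock-down steady states, a
#' held-out noise-free double knock-out truth table, and the gold-standard
#' topology (the nonzero pattern of the adjacency matrix).
#' Expression-proportional noise is applied to every released matrix except
#' the double knock-out truth.
#'
#' @param net A `synthetic_network` from [generate_topology()].
#' @param config A [sim_config()].
#' @return A `dream4_dataset` list: `ts` (list of experiments), `wt`
#'   (genes x (n_series + 1) matrix), `ko` and `kd` (each `expr` + `komap`),
#'   `double_ko` (`pairs` data frame and `truth` genes x pairs matrix),
#'   `gold` ([gold_standard()]), `wt_true` (noise-free wild type), `net`,
#'   `config`.
#' @export
simulate_dream4_dataset <- function(net, config = sim_config()) {
  n <- net$n_genes
  genes <- net$genes
  x_wt <- simulate_steady_state(net)
  with_seed(config$seed, {
    # time series: perturbation phase then relaxation phase
    ts <- list()
    wt_first <- matrix(0, n, config$n_series, dimnames = list(genes, NULL))
    for (s in seq_len(config$n_series)) {
      n_shift <- max(1L, round(config$perturb_fraction * n))
      shifted <- sample.int(n, n_shift)
      fac <- exp(stats::runif(n_shift, log(config$perturb_range[[1L]]),
                              log(config$perturb_range[[2L]])))
      basal_p <- net$basal
      basal_p[shifted] <- basal_p[shifted] * fac
      pert <- integrate_phase(net, x_wt, config$points_per_phase, config$dt,
                              basal = basal_p)
      relax <- integrate_phase(net, pert[, ncol(pert)],
                               config$points_per_phase, config$dt)
      pert_n <- apply_noise(pert, config$noise_coeff, config$noise_floor)
      relax_n <- apply_noise(relax, config$noise_coeff, config$noise_floor)
      tt <- seq(0, by = config$dt, length.out = config$points_per_phase)
      ts[[length(ts) + 1L]] <- list(time = tt, values = pert_n)
      ts[[length(ts) + 1L]] <- list(time = tt, values = relax_n)
      wt_first[, s] <- pert_n[, 1L]
    }
    # wild-type block: series starts + one provided profile (11 by default)
    wt_extra <- apply_noise(matrix(x_wt, ncol = 1,
                                   dimnames = list(genes, NULL)),
                            config$noise_coeff, config$noise_floor)
    wt <- cbind(wt_first, wt_extra)
    colnames(wt) <- paste0("WT", seq_len(ncol(wt)))
    # per-gene knock-out / knock-down steady states
    ko_true <- sapply(genes, function(g) simulate_steady_state(net, ko_genes = g))
    kd_true <- sapply(genes, function(g) {
      simulate_steady_state(net, kd_genes = g, kd_factor = config$kd_factor)
    })
    colnames(ko_true) <- paste0("KO_", genes)
    colnames(kd_true) <- paste0("KD_", genes)
    ko <- apply_noise(ko_true, config$noise_coeff, config$noise_floor)
    kd <- apply_noise(kd_true, config$noise_coeff, config$noise_floor)
    ko[cbind(seq_len(n), seq_len(n))] <- 0  # a knocked-out gene reads zero
    komap <- stats::setNames(seq_len(n), genes)
    # double knock-out truth (noise-free, held out)
    pair_idx <- which(upper.tri(matrix(0, n, n)))
    chosen <- sample(pair_idx, config$n_double_ko)
    p <- row(matrix(0, n, n))[chosen]
    q <- col(matrix(0, n, n))[chosen]
    truth <- matrix(0, n, config$n_double_ko,
                    dimnames = list(genes, paste0("DKO", seq_along(chosen))))
    for (k in seq_along(chosen)) {
      truth[, k] <- simulate_steady_state(net,
                                          ko_genes = genes[c(p[[k]], q[[k]])])
    }
    pairs <- data.frame(gene_a = genes[p], gene_b = genes[q],
                        stringsAsFactors = FALSE)
    # gold standard = nonzero adjacency pattern (regulator j -> target i)
    nz <- which(net$adjacency != 0, arr.ind = TRUE)
    gold <- gold_standard(
      data.frame(regulator = genes[nz[, "col"]], target = genes[nz[, "row"]],
                 stringsAsFactors = FALSE), genes)
    structure(list(
      ts = ts, wt = wt,
      ko = list(expr = ko, komap = komap),
      kd = list(expr = kd, komap = komap),
      double_ko = list(pairs = pairs, truth = truth),
      gold = gold, wt_true = x_wt, net = net, config = config
    ), class = "dream4_dataset")
  })
}

#' Write a simulated dataset to DREAM4-dialect files
#'
#' Writes the time series, wild-type, knock-out and knock-down blocks, the
#' gold standard, the double knock-out pair list and truth table, and a
#' YAML echo of the simulation configuration (including the seed).
#'
#' @param dataset A `dream4_dataset` from [simulate_dream4_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dream4_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    timeseries = file.path(dir, "timeseries.tsv"),
    wildtype = file.path(dir, "wildtype.tsv"),
    knockouts = file.path(dir, "knockouts.tsv"),
    knockdowns = file.path(dir, "knockdowns.tsv"),
    goldstandard = file.path(dir, "goldstandard.tsv"),
    dko_pairs = file.path(dir, "dko_pairs.tsv"),
    dko_truth = file.path(dir, "dko_truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_time_series_table(dataset$ts, paths[["timeseries"]])
  write_steady_state_table(dataset$wt, paths[["wildtype"]])
  write_steady_state_table(dataset$ko$expr, paths[["knockouts"]])
  write_steady_state_table(dataset$kd$expr, paths[["knockdowns"]])
  write_gold_standard(dataset$gold, paths[["goldstandard"]])
  writeLines(sprintf("%s\t%s", dataset$double_ko$pairs$gene_a,
                     dataset$double_ko$pairs$gene_b), paths[["dko_pairs"]])
  write_steady_state_table(dataset$double_ko$truth, paths[["dko_truth"]])
  cfg <- unclass(dataset$config)
  cfg$n_genes <- dataset$net$n_genes
  cfg$network_seed <- dataset$net$seed
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
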