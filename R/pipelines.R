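#' Build the response design for a benchmark dataset
#'
#' Convenience wrapper combining a dataset's time series with its merged
#' steady-state blocks (knock-out, knock-down, wild-type) into the shared
#' regression/MI design.
#'
#' @param dataset A `dream4_dataset`.
#' @param tau_half,lags,alpha_convention Passed to
#'   [build_response_design()].
#' @return A `response_design`.
#' @export
dataset_design <- function(dataset, tau_half = 50, lags = c(1L, 2L),
                           alpha_convention = "half_life") {
  build_response_design(dataset$ts,
                        list(dataset$ko$expr, dataset$kd$expr, dataset$wt),
                        tau_half = tau_half, lags = lags,
                        alpha_convention = alpha_convention)
}

#' Run the four network-inference pipelines on one dataset
#'
#' Executes, in order: MCZ on the knock-out block (pipeline 1); tlCLR and
#' the Inferelator-style constrained regression on the response design,
#' combined by rank transplant (pipeline 2); the rank-transplant
#' combination of pipeline 2 with MCZ (pipeline 3); and, when `M > 0`, the
#' column-bootstrap resampling ensemble aggregated by median rank
#' (pipeline 4).
#'
#' @param dataset A `dream4_dataset` (simulated or read from files).
#' @param K Maximum candidate regulators per gene.
#' @param K_folds CV folds for shrinkage selection.
#' @param s_grid Shrinkage grid.
#' @param n_bins MI bins.
#' @param tau_half,lags Design parameters.
#' @param filter_percentile Lower MCZ percentile removed before
#'   combination.
#' @param M Resamples for pipeline 4 (0 skips it).
#' @param seed Base seed for CV folds and resampling.
#' @return A `grn_result` list: confidence matrices `Z_mcz`, `Z_tlclr`,
#'   `Z_inf`, `Z_p2`, `Z_p3`, optionally `Z_p4`; dynamical models
#'   `model_p3` and optionally `model_p4`; plus `est`, `mask`, `rd`.
#' @export
grn_pipelines <- function(dataset, K = 10L, K_folds = 10L,
                          s_grid = seq(0, 1, by = 0.05), n_bins = 10L,
                          tau_half = 50, lags = c(1L, 2L),
                          filter_percentile = 20, M = 0L, seed = 1L) {
  est <- corrected_wildtype(dataset$wt, dataset$ko$expr)
  Z_mcz <- mcz_scores(dataset$ko$expr, dataset$ko$komap, est)
  mask <- mcz_filter_mask(Z_mcz, filter_percentile)
  rd <- dataset_design(dataset, tau_half = tau_half, lags = lags)
  member <- pipeline3_member(rd, Z_mcz, mask, K = K, K_folds = K_folds,
                             s_grid = s_grid, n_bins = n_bins, seed = seed)
  out <- list(Z_mcz = Z_mcz, Z_tlclr = member$Z_tlclr, Z_inf = member$Z_inf,
              Z_p2 = member$Z_p2, Z_p3 = member$Z_p3,
              model_p3 = member$model, est = est, mask = mask, rd = rd)
  if (M > 0L) {
    ens <- run_resampling_pipeline(rd, Z_mcz, mask, M = M, K = K,
                                   K_folds = K_folds, s_grid = s_grid,
                                   n_bins = n_bins, seed = seed)
    med <- ensemble_medians(ens)
    out$Z_p4 <- med$Z
    out$model_p4 <- med$model
    out$ensemble <- ens
  }
  structure(out, class = "grn_result")
}

#' Benchmark configuration
#'
#' Defaults mirror the DREAM4 100-gene design: 5 networks of 100 genes,
#' 10 perturbation series, per-gene knock-outs and knock-downs, 20 double
#' knock-out pairs per network.  Every count is configurable; small values
#' give fast smoke runs.
#'
#' @param n_networks Number of synthetic networks.
#' @param n_genes Genes per network.
#' @param mean_in_degree Expected regulators per gene.
#' @param sim Arguments forwarded to [sim_config()] (list).
#' @param K,K_folds,n_bins,filter_percentile,M Pipeline parameters.
#' @param dko_init Initial-condition mode for double knock-out prediction.
#' @param seed Top-level seed; every random draw derives from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_networks = 5L, n_genes = 100L,
                             mean_in_degree = 2, sim = list(),
                             K = 10L, K_folds = 10L, n_bins = 10L,
                             filter_percentile = 20, M = 200L,
                             dko_init = "single_ko_weighted", seed = 1L) {
  structure(list(n_networks = as.integer(n_networks),
                 n_genes = as.integer(n_genes),
                 mean_in_degree = mean_in_degree, sim = sim, K = as.integer(K),
                 K_folds = as.integer(K_folds), n_bins = as.integer(n_bins),
                 filter_percentile = filter_percentile, M = as.integer(M),
                 dko_init = dko_init, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run the full synthetic benchmark
#'
#' Generates `n_networks` synthetic datasets, runs all four pipelines on
#' each, scores every pipeline's ranking by AUPR against the network's
#' gold standard, and evaluates double knock-out predictions (pipeline-3
#' model) by MSE.  With an output directory, all data blocks, ranked edge
#' lists and report tables are written alongside a YAML configuration echo.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional output directory.
#' @return A list: `aupr` (networks x pipelines data frame), `dko_mse`
#'   (per-network mean MSE and per-pair values), `config`.
#' @export
run_full_benchmark <- function(config = benchmark_config(), out_dir = NULL) {
  aupr_rows <- list()
  dko_rows <- list()
  for (net_i in seq_len(config$n_networks)) {
    net_seed <- config$seed + 1000L * net_i
    net <- generate_topology(config$n_genes, config$mean_in_degree,
                             seed = net_seed)
    sim_args <- config$sim
    sim_args$seed <- net_seed + 1L
    cfg <- do.call(sim_config, sim_args)
    dataset <- simulate_dream4_dataset(net, cfg)
    res <- grn_pipelines(dataset, K = config$K, K_folds = config$K_folds,
                         n_bins = config$n_bins,
                         filter_percentile = config$filter_percentile,
                         M = config$M, seed = net_seed + 2L)
    mats <- list(mcz = res$Z_mcz, pipeline2 = res$Z_p2,
                 pipeline3 = res$Z_p3)
    if (!is.null(res$Z_p4)) mats$pipeline4 <- res$Z_p4
    scores <- vapply(mats, function(Z) aupr(ranked_edges(Z), dataset$gold),
                     numeric(1))
    aupr_rows[[net_i]] <- data.frame(network = net_i, t(scores))
    preds <- lapply(seq_len(nrow(dataset$double_ko$pairs)), function(k) {
      pair <- unlist(dataset$double_ko$pairs[k, c("gene_a", "gene_b")],
                     use.names = FALSE)
      x0 <- initial_conditions(dataset$ko$expr, dataset$ko$komap, res$Z_mcz,
                               pair, mode = config$dko_init, est = res$est)
      predict_double_ko(res$model_p3, x0, pair)
    })
    ev <- evaluate_double_ko(preds, dataset$double_ko$truth)
    dko_rows[[net_i]] <- data.frame(network = net_i, mean_mse = ev$mean)
    if (!is.null(out_dir)) {
      nd <- file.path(out_dir, sprintf("network%02d", net_i))
      write_dream4_dataset(dataset, nd)
      for (nm in names(mats)) {
        write_ranked_edges(mats[[nm]], file.path(nd, paste0(nm, "_ranked.tsv")))
      }
    }
  }
  report <- list(aupr = do.call(rbind, aupr_rows),
                 dko_mse = do.call(rbind, dko_rows), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$aupr, file.path(out_dir, "aupr_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$dko_mse, file.path(out_dir, "dko_mse_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  report
}
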