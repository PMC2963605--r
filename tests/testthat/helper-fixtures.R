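# Shared fixtures: small simulated datasets are cached per test run so
# expensive generation happens once.

fixture_env <- new.env(parent = emptyenv())

# 20-gene DREAM4-design dataset with default noise (c = 0.1).
small_noisy_dataset <- function() {
  if (is.null(fixture_env$noisy)) {
    net <- generate_topology(20, mean_in_degree = 2, seed = 101)
    fixture_env$noisy <- simulate_dream4_dataset(net, sim_config(seed = 202))
  }
  fixture_env$noisy
}

# 20-gene dataset with observational noise switched off.
small_clean_dataset <- function() {
  if (is.null(fixture_env$clean)) {
    net <- generate_topology(20, mean_in_degree = 2, seed = 101)
    fixture_env$clean <- simulate_dream4_dataset(
      net, sim_config(noise_coeff = 0, noise_floor = 0, seed = 202))
  }
  fixture_env$clean
}

# Independent plug-in MI oracle: quantile binning re-derived from sorted
# positions, entropies summed explicitly over the joint table.
oracle_mi <- function(a, b, n_bins) {
  if (length(unique(a)) <= 1L || length(unique(b)) <= 1L) return(0)
  bin_of <- function(x) {
    n <- length(x)
    pos <- integer(n)
    pos[order(x, seq_len(n))] <- seq_len(n)  # stable order statistics
    as.integer(ceiling(pos * n_bins / n))
  }
  tab <- table(factor(bin_of(a), levels = seq_len(n_bins)),
               factor(bin_of(b), levels = seq_len(n_bins)))
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  total <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (pa[[i]] * pb[[j]]))
      }
    }
  }
  total
}

# Brute-force stepwise AUPR oracle: precision/recall recomputed from
# scratch at every list depth.
oracle_aupr <- function(ranked_df, gold) {
  genes <- gold$genes
  n <- length(genes)
  code <- function(r, t) (match(r, genes) - 1L) * n + match(t, genes)
  listed <- code(ranked_df$regulator, ranked_df$target)
  all_pairs <- expand.grid(target = seq_len(n), regulator = seq_len(n))
  all_pairs <- all_pairs[all_pairs$target != all_pairs$regulator, ]
  all_pairs <- all_pairs[order(all_pairs$regulator, all_pairs$target), ]
  all_codes <- (all_pairs$regulator - 1L) * n + all_pairs$target
  full <- c(listed, setdiff(all_codes, listed))
  gold_codes <- code(gold$edges$regulator, gold$edges$target)
  n_true <- length(gold_codes)
  area <- 0
  prev_recall <- 0
  for (k in seq_along(full)) {
    tp <- sum(full[seq_len(k)] %in% gold_codes)
    precision <- tp / k
    recall <- tp / n_true
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}
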