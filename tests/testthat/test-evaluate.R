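test_that("a perfect ranking scores AUPR exactly 1", {
  ds <- small_noisy_dataset()
  gold <- ds$gold
  genes <- gold$genes
  Z <- matrix(0, 20, 20, dimnames = list(genes, genes))
  Z[cbind(match(gold$edges$target, genes),
          match(gold$edges$regulator, genes))] <- 1
  expect_identical(aupr(ranked_edges(Z), gold), 1)

  # single gold edge ranked first of P
  g1 <- gold_standard(data.frame(regulator = "G1", target = "G2"),
                      paste0("G", 1:5))
  r1 <- data.frame(regulator = "G1", target = "G2", score = 1)
  expect_identical(aupr(r1, g1), 1)

  empty <- gold_standard(data.frame(regulator = character(0),
                                    target = character(0)), genes)
  expect_error(aupr(ranked_edges(Z), empty), "no edges")
})

test_that("AUPR agrees with the brute-force threshold-sweep oracle", {
  set.seed(61)
  for (rep in 1:4) {
    n <- 7
    genes <- paste0("G", 1:n)
    Z <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
    diag(Z) <- 0
    n_edges <- sample(3:10, 1)
    idx <- which(row(Z) != col(Z))
    pick <- sample(idx, n_edges)
    gold <- gold_standard(
      data.frame(regulator = genes[col(Z)[pick]],
                 target = genes[row(Z)[pick]]), genes)
    ranked <- ranked_edges(Z)
    expect_equal(aupr(ranked, gold), oracle_aupr(ranked, gold),
                 tolerance = 1e-9)
    # prefix-only lists score identically once zeros are appended
    expect_equal(aupr(ranked[ranked$score > 0.5, ], gold),
                 oracle_aupr(ranked[ranked$score > 0.5, ], gold),
                 tolerance = 1e-9)
  }
})

test_that("AUPR is invariant to strictly monotone score transforms", {
  set.seed(62)
  n <- 8
  genes <- paste0("G", 1:n)
  Z <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
  diag(Z) <- 0
  idx <- sample(which(row(Z) != col(Z)), 9)
  gold <- gold_standard(data.frame(regulator = genes[col(Z)[idx]],
                                   target = genes[row(Z)[idx]]), genes)
  a1 <- aupr(ranked_edges(Z), gold)
  a2 <- aupr(ranked_edges(exp(3 * Z)), gold)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("random rankings score near the edge density on sparse networks", {
  set.seed(63)
  n <- 20
  genes <- paste0("G", 1:n)
  idx_all <- which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
  pick <- sample(idx_all, 15)
  gold <- gold_standard(
    data.frame(regulator = genes[col(matrix(0, n, n))[pick]],
               target = genes[row(matrix(0, n, n))[pick]]), genes)
  density <- 15 / gold$universe  # 0.039
  vals <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    Z <- matrix(0, n, n, dimnames = list(genes, genes))
    Z[idx_all] <- sample(length(idx_all))
    aupr(ranked_edges(Z), gold)
  })
  # mean sits at the density up to the finite-list bias ~ (T+1)/(P+1)
  expect_lt(abs(mean(vals) - density), 0.02)
  expect_lt(mean(vals), 0.1)  # "close to zero" for a sparse gold standard
})

test_that("relative ranks are positions over P with the exact limits", {
  genes <- paste0("G", 1:4)
  gold <- gold_standard(data.frame(regulator = c("G1", "G3"),
                                   target = c("G2", "G4")), genes)
  Z <- matrix(0, 4, 4, dimnames = list(genes, genes))
  Z[2, 1] <- 5  # top-ranked true edge G1 -> G2
  rr <- relative_ranks(ranked_edges(Z), gold)
  expect_equal(unname(rr["G1->G2"]), 1 / 12)
  # the other true edge sits wherever the zero-score tie order puts it
  expect_gte(rr[["G3->G4"]], 1 / 12)
  expect_lte(max(rr), 1)

  # bottom-ranked edge has relative rank exactly 1
  Zb <- matrix(2, 4, 4, dimnames = list(genes, genes))
  Zb[4, 3] <- 1  # G3 -> G4 strictly last
  rrb <- relative_ranks(ranked_edges(Zb), gold)
  expect_equal(unname(rrb["G3->G4"]), 1)
})

test_that("median relative rank improves as noise vanishes", {
  net <- generate_topology(20, 2, seed = 101)
  meds <- sapply(c(0.5, 0), function(noise) {
    ds <- simulate_dream4_dataset(net, sim_config(noise_coeff = noise,
                                                  noise_floor = 0,
                                                  seed = 303))
    est <- corrected_wildtype(ds$wt, ds$ko$expr)
    Z <- mcz_scores(ds$ko$expr, ds$ko$komap, est)
    median(relative_ranks(ranked_edges(Z), ds$gold))
  })
  expect_lt(meds[[2]], meds[[1]])
})

test_that("expression bins are equal-count and reduce to relative ranks", {
  ds <- small_noisy_dataset()
  est <- corrected_wildtype(ds$wt, ds$ko$expr)
  Z <- mcz_scores(ds$ko$expr, ds$ko$komap, est)
  ranked <- ranked_edges(Z)
  one <- binned_error_by_regulator_expression(ranked, ds$gold, ds$ko$expr,
                                              ds$ko$komap, n_bins = 1)
  rr <- relative_ranks(ranked, ds$gold)
  expect_setequal(unname(one$bins[[1]]), unname(rr))

  # 14 regulators into 7 bins -> exactly 2 per bin
  genes <- paste0("G", 1:15)
  gold14 <- gold_standard(
    data.frame(regulator = genes[1:14], target = rep("G15", 14)), genes)
  X_ko <- matrix(rexp(15 * 15), 15, 15, dimnames = list(genes, NULL))
  Zr <- matrix(runif(225), 15, 15, dimnames = list(genes, genes))
  diag(Zr) <- 0
  b <- binned_error_by_regulator_expression(ranked_edges(Zr), gold14, X_ko,
                                            setNames(1:15, genes),
                                            n_bins = 7)
  expect_equal(unname(table(b$regulator_bins$bin)), rep(2L, 7),
               ignore_attr = TRUE)
})
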