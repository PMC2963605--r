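test_that("rank transplant follows the worked 3x3 trace", {
  # A has off-diagonal values {9, 7, 5, 3, 2, 1}; B ranks three edges
  A <- matrix(0, 3, 3)
  A[1, 2] <- 9; A[1, 3] <- 7; A[2, 1] <- 5
  A[2, 3] <- 3; A[3, 1] <- 2; A[3, 2] <- 1
  B <- matrix(0, 3, 3)
  B[3, 1] <- 10; B[2, 3] <- 6; B[1, 2] <- 4
  out <- rank_transplant_combine(A, B)
  # transplanted B': (3,1) <- 9, (2,3) <- 7, (1,2) <- 5; combined = A + B'
  expect_equal(out[3, 1], 2 + 9)
  expect_equal(out[2, 3], 3 + 7)
  expect_equal(out[1, 2], 9 + 5)
  expect_equal(out[1, 3], 7 + 0)
  expect_equal(out[2, 1], 5 + 0)
  expect_equal(out[3, 2], 1 + 0)
  expect_true(all(diag(out) == 0))
})

test_that("rank transplant degenerate cases", {
  set.seed(2)
  A <- matrix(runif(16), 4, 4); diag(A) <- 0
  # B = A: combined doubles every entry, preserving A's ordering
  out <- rank_transplant_combine(A, A)
  off <- row(A) != col(A)
  expect_equal(order(out[off]), order(2 * A[off]))
  expect_equal(out[off], 2 * A[off], tolerance = 1e-12)

  # single nonzero entry in B receives A's maximum value
  B1 <- matrix(0, 4, 4); B1[2, 4] <- 0.01
  out1 <- rank_transplant_combine(A, B1)
  expect_equal(out1[2, 4], A[2, 4] + max(A))

  # empty B leaves A unchanged
  expect_equal(rank_transplant_combine(A, matrix(0, 4, 4)), A,
               ignore_attr = TRUE)

  # all-zero reference transplants zeros
  expect_true(all(rank_transplant_combine(matrix(0, 4, 4), A) == 0))

  # more nonzero entries in B than positive values in A: overflow gets
  # A's smallest positive value
  A2 <- matrix(0, 3, 3); A2[1, 2] <- 5; A2[2, 1] <- 3
  B2 <- matrix(0, 3, 3); B2[1, 3] <- 9; B2[3, 1] <- 8; B2[2, 3] <- 7
  out2 <- rank_transplant_combine(A2, B2)
  expect_equal(out2[1, 3], 5)  # rank 1 -> A's max
  expect_equal(out2[3, 1], 3)  # rank 2 -> A's 2nd
  expect_equal(out2[2, 3], 3)  # overflow -> A's smallest positive
})

test_that("pipeline-3 combination reduces to MCZ when pipeline 2 is empty", {
  set.seed(3)
  Zm <- matrix(runif(25), 5, 5); diag(Zm) <- 0
  expect_equal(pipeline3_combine(matrix(0, 5, 5), Zm), Zm,
               ignore_attr = TRUE)
  expect_true(all(pipeline3_combine(Zm, matrix(0, 5, 5)) == 0))
})

test_that("bootstrap resamples preserve pairing and are seed-reproducible", {
  lin <- simulate_linear_dataset(n_genes = 6, seed = 14)
  rd <- build_response_design(lin$ts, list(lin$ko$expr), lags = c(1, 2))
  b1 <- bootstrap_columns(rd, seed = 9)
  b2 <- bootstrap_columns(rd, seed = 9)
  expect_identical(b1$Y, b2$Y)
  expect_identical(b1$obs_kind, b2$obs_kind)
  expect_equal(ncol(b1$Y), ncol(rd$Y))
  # every resampled column is an original (Y, X) column pair
  orig <- paste(apply(rd$Y, 2, paste, collapse = ","),
                apply(rd$X, 2, paste, collapse = ","))
  boot <- paste(apply(b1$Y, 2, paste, collapse = ","),
                apply(b1$X, 2, paste, collapse = ","))
  expect_true(all(boot %in% orig))
})

test_that("bootstrap draws about 1 - 1/e distinct columns", {
  lin <- simulate_linear_dataset(n_genes = 4, n_series = 30, seed = 15)
  rd <- build_response_design(lin$ts, list(), lags = 1)
  n <- ncol(rd$Y)  # 300 columns
  fracs <- sapply(1:20, function(s) {
    b <- bootstrap_columns(rd, seed = s)
    length(unique(apply(b$X, 2, paste, collapse = ","))) / n
  })
  expect_lt(abs(mean(fracs) - (1 - exp(-1))), 0.03)
})

test_that("a forced identity resample reproduces the plain pipeline-3 run", {
  ds <- small_noisy_dataset()
  est <- corrected_wildtype(ds$wt, ds$ko$expr)
  Z_mcz <- mcz_scores(ds$ko$expr, ds$ko$komap, est)
  mask <- mcz_filter_mask(Z_mcz, 20)
  rd <- dataset_design(ds)
  ens <- run_resampling_pipeline(rd, Z_mcz, mask, M = 1, seed = 40,
                                 resampler = function(rd, seed) rd)
  direct <- grnpipe:::pipeline3_member(rd, Z_mcz, mask, seed = 41)
  expect_equal(ens$members[[1]]$Z_p3, direct$Z_p3, tolerance = 1e-12)
  expect_equal(ens$members[[1]]$model$beta, direct$model$beta,
               tolerance = 1e-12)
  # and the degenerate ensemble median preserves the member ordering
  med <- ensemble_medians(ens)
  off <- row(med$Z) != col(med$Z)
  expect_equal(order(-med$Z[off]), order(-direct$Z_p3[off]))
})

test_that("resampling runs are byte-identical across repeats", {
  ds <- small_noisy_dataset()
  est <- corrected_wildtype(ds$wt, ds$ko$expr)
  Z_mcz <- mcz_scores(ds$ko$expr, ds$ko$komap, est)
  rd <- dataset_design(ds)
  e1 <- run_resampling_pipeline(rd, Z_mcz, NULL, M = 2, seed = 77)
  e2 <- run_resampling_pipeline(rd, Z_mcz, NULL, M = 2, seed = 77)
  expect_identical(e1$members[[2]]$Z_p3, e2$members[[2]]$Z_p3)
  expect_identical(e1$members[[1]]$model$beta, e2$members[[1]]$model$beta)
})

test_that("ensemble medians median ranks and parameters edge-wise", {
  genes <- paste0("G", 1:3)
  mk <- function(vals, beta_edge) {
    Z <- matrix(0, 3, 3, dimnames = list(genes, genes))
    Z[row(Z) != col(Z)] <- vals
    beta <- matrix(0, 3, 3, dimnames = list(genes, genes))
    beta[1, 2] <- beta_edge
    model <- structure(list(beta = beta,
                            bias = setNames(c(1, 2, 3), genes),
                            h = setNames(c(0.5, 0.5, 0.5), genes),
                            alpha = 0.01, regressor_stats = NULL),
                       class = "dynamical_model")
    list(Z_p3 = Z, model = model)
  }
  # edge (1,2) holds member ranks {1, 5, 6} -> median rank 5
  m1 <- mk(c(6, 1, 2, 5, 3, 4), 0)
  m1$Z_p3[] <- 0; m1$Z_p3[1, 2] <- 10; m1$Z_p3[2, 1] <- 1  # rank 1 for (1,2)
  m2 <- mk(6:1, 0)     # ranks follow positions
  m3 <- mk(1:6, 0.6)
  ens <- structure(list(members = list(m1, m2, m3), M = 3, seed = 1),
                   class = "network_ensemble")
  med <- ensemble_medians(ens)
  r1 <- rank(-m1$Z_p3[row(m1$Z_p3) != col(m1$Z_p3)], ties.method = "average")
  r2 <- rank(-m2$Z_p3[row(m2$Z_p3) != col(m2$Z_p3)], ties.method = "average")
  r3 <- rank(-m3$Z_p3[row(m3$Z_p3) != col(m3$Z_p3)], ties.method = "average")
  med_rank <- apply(rbind(r1, r2, r3), 2, median)
  off <- which(row(med$Z) != col(med$Z))
  expect_equal(med$Z[off], 6 + 1 - med_rank, ignore_attr = TRUE)
  # beta values {0, 0, 0.6} -> sparse median 0
  expect_equal(med$model$beta[1, 2], 0)
  expect_equal(unname(med$model$bias), c(1, 2, 3))
})

test_that("identical members give back the member model and ordering", {
  ds <- small_noisy_dataset()
  est <- corrected_wildtype(ds$wt, ds$ko$expr)
  Z_mcz <- mcz_scores(ds$ko$expr, ds$ko$komap, est)
  rd <- dataset_design(ds)
  member <- grnpipe:::pipeline3_member(rd, Z_mcz, NULL, seed = 50)
  ens <- structure(list(members = list(
    list(Z_p3 = member$Z_p3, model = member$model),
    list(Z_p3 = member$Z_p3, model = member$model),
    list(Z_p3 = member$Z_p3, model = member$model)), M = 3, seed = 1),
    class = "network_ensemble")
  med <- ensemble_medians(ens)
  off <- row(med$Z) != col(med$Z)
  expect_equal(order(-med$Z[off]), order(-member$Z_p3[off]))
  expect_equal(med$model$beta, member$model$beta)
})
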