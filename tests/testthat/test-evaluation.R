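test_that("cosine similarity handles parallel, orthogonal and zero vectors", {
  Y <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  Yh <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 0, 0))
  cs <- cosine_similarity_series(Y, Yh)
  expect_equal(cs$values[1:3], c(1, 0, sqrt(2) / 2), tolerance = 1e-12)
  expect_false(cs$mask[4])
  expect_equal(cs$n_used, 3L)
  expect_equal(cs$n_skipped, 1L)
  expect_error(cosine_similarity_series(Y, Yh[1:2, ]), "shape")
})

test_that("distribution summaries use linear-interpolation quantiles", {
  s <- summarize_distribution(rep(0.5, 9))
  expect_equal(c(s$q1, s$median, s$q3), c(0.5, 0.5, 0.5))
  s2 <- summarize_distribution(as.numeric(1:100))
  expect_equal(s2$median, 50.5)
  set.seed(601)
  v <- rnorm(37)
  s3 <- summarize_distribution(v)
  expect_equal(c(s3$q1, s3$median, s3$q3),
               as.numeric(quantile(v, c(0.25, 0.5, 0.75), type = 7)),
               tolerance = 1e-12)
  expect_true(s3$q1 <= s3$median && s3$median <= s3$q3)
  expect_error(summarize_distribution(c(NA, NA)), "no unmasked")
})

test_that("sparsity index counts exactly-zero slices per mode", {
  beta <- array(1, dim = c(2, 3, 4, 2))
  expect_equal(sparsity_index(beta, 3)$percent_zero_slices, 0)
  beta[, , c(1, 3), ] <- 0
  sp <- sparsity_index(beta, 3)
  expect_equal(sp$percent_zero_slices, 50)
  expect_equal(sp$zero_slice_indices, c(1L, 3L))
  expect_equal(sparsity_index(array(0, dim = c(2, 2, 2, 1)), 2)$percent_zero_slices,
               100)
  # a single surviving coefficient keeps the slice
  beta2 <- array(0, dim = c(2, 2, 4, 1)); beta2[1, 1, 2, 1] <- 1e-300
  expect_equal(sparsity_index(beta2, 3)$zero_slice_indices, c(1L, 3L, 4L))
  expect_error(sparsity_index(array(1, dim = c(2, 2, 2)), 1), "order-4")
})

test_that("the 48-of-64 arithmetic gives 75 percent sparsity", {
  beta <- array(1, dim = c(10, 15, 64, 3))
  beta[, , 17:64, ] <- 0
  expect_equal(sparsity_index(beta, 3)$percent_zero_slices, 75)
})

test_that("pseudo-online runs are deterministic and causal", {
  st <- make_stream(n = 120, block = 20)
  tr <- st$session$blocks[1:4]; te <- st$session$blocks[5:6]
  pc <- penalty_config()
  r1 <- pseudo_online_experiment(tr, te, pc, dims = c(3, 4, 8), J = 2, F = 4)
  r2 <- pseudo_online_experiment(tr, te, pc, dims = c(3, 4, 8), J = 2, F = 4)
  expect_identical(r1$cossim$median, r2$cossim$median)
  expect_identical(r1$sparsity$percent_zero_slices,
                   r2$sparsity$percent_zero_slices)
  expect_length(r1$f_star_trajectory, 4L)
  # training on zero-target blocks yields a degenerate stream: the model
  # cannot produce meaningful directions and most samples are masked
  tr0 <- lapply(tr, function(b)
    observation_block(b$X, matrix(0, b$n, 2), dims = b$dims))
  te0 <- lapply(te, function(b)
    observation_block(b$X, matrix(0, b$n, 2), dims = b$dims))
  r0 <- pseudo_online_experiment(tr0, te0, pc, dims = c(3, 4, 8), J = 2, F = 4)
  expect_equal(r0$cos_values$n_used, 0L)
})

test_that("default lambda grids have 26 points with a lambda = 0 baseline", {
  g0 <- default_lambda_grid(0)
  g5 <- default_lambda_grid(0.5)
  g1 <- default_lambda_grid(1)
  expect_length(g0, 26L)
  expect_length(g5, 26L)
  expect_identical(g5, g1)
  expect_equal(g0[1:3], c(0, 0.002, 0.004))
  expect_equal(max(g0), 0.05)
  expect_equal(max(g1), 0.5)
  expect_equal(g0[1], 0)
})

test_that("the lambda = 0 sweep row equals the standalone baseline", {
  st <- make_stream(n = 120, block = 20)
  tr <- st$session$blocks[1:4]; te <- st$session$blocks[5:6]
  sw <- lambda_sweep(tr, te, p = 1, lam_grid = c(0, 0.2),
                     dims = c(3, 4, 8), J = 2, F = 4)
  base <- pseudo_online_experiment(tr, te, penalty_config(),
                                   dims = c(3, 4, 8), J = 2, F = 4)
  expect_identical(sw$table$median[1], base$cossim$median)
  expect_identical(sw$table$sparsity_percent[1],
                   base$sparsity$percent_zero_slices)
  expect_identical(sw$table$f_star[1], base$f_star)
  expect_equal(nrow(sw$table), 2L)
  expect_error(lambda_sweep(tr, te, p = 1, lam_grid = numeric(0),
                            dims = c(3, 4, 8), J = 2), "nonempty")
})

test_that("paired signed-rank comparison matches its reference behaviour", {
  set.seed(602)
  a <- rnorm(50)
  same <- paired_signed_rank_compare(a, a)
  expect_true(same$no_difference)
  expect_false(same$significant)
  shift <- paired_signed_rank_compare(a, a + 1)
  expect_true(shift$significant)
  expect_lt(shift$p_value, 1e-6)
  # Bonferroni threshold for 31 comparisons at alpha = 0.05
  bc <- paired_signed_rank_compare(a, a + rnorm(50), alpha = 0.05,
                                   n_comparisons = 31)
  expect_equal(bc$alpha_bonferroni, 0.05 / 31)
  expect_equal(round(bc$alpha_bonferroni, 5), 0.00161)
  # small-n exact path agrees with the exact signed-rank null: n = 6, all
  # positive differences -> two-sided p = 2 / 2^6
  b6 <- c(0.13, 0.21, 0.34, 0.42, 0.55, 0.69)
  ex <- paired_signed_rank_compare(numeric(6), b6)
  expect_equal(ex$p_value, 2 / 64, tolerance = 1e-12)
  expect_error(paired_signed_rank_compare(1:3, 1:4), "equal length")
})
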