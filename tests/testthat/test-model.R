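test_that("initialization gives the zero model and validates inputs", {
  m <- rewnpls_init(c(3, 4, 5), J = 2, F = 3)
  expect_equal(m$UI, 0L)
  expect_equal(predict(m, rand_tensor(c(3, 4, 5))), matrix(0, 1, 2))
  expect_error(rewnpls_init(c(3, 4, 5), J = 2, mu1 = 1.5), "mu1")
  expect_error(rewnpls_init(c(3, 4, 5), J = 2, mu1 = 0), "mu1")
  expect_error(rewnpls_init(c(3, 4, 5), J = 2, F = 0), "F")
  m1 <- rewnpls_init(c(3, 4, 5), J = 2, F = 1)
  expect_length(m1$beta, 1L)
  expect_equal(prod(rewnpls_init(c(10, 15, 64), J = 3)$dims), 9600)
})

test_that("normalization statistics pool exactly when mu1 = 1", {
  set.seed(401)
  dims <- c(2, 3, 2); D <- prod(dims)
  X1 <- matrix(rnorm(40 * D, mean = 2, sd = 3), 40)
  X2 <- matrix(rnorm(60 * D, mean = -1, sd = 0.5), 60)
  Y1 <- matrix(rnorm(40 * 2), 40); Y2 <- matrix(rnorm(60 * 2), 60)
  m <- rewnpls_init(dims, J = 2, mu1 = 1)
  m <- update_normalization(m, observation_block(X1, Y1, dims = dims))
  m <- update_normalization(m, observation_block(X2, Y2, dims = dims))
  Xall <- rbind(X1, X2)
  expect_equal(m$mean_x, colMeans(Xall), tolerance = 1e-12)
  # population (1/n) variance is what the exponentially weighted sums give
  vpop <- colMeans(Xall^2) - colMeans(Xall)^2
  expect_equal(m$scale_x, sqrt(vpop), tolerance = 1e-10)
  expect_equal(m$mean_y, colMeans(rbind(Y1, Y2)), tolerance = 1e-12)
})

test_that("constant features get centered with the scale clamp engaged", {
  dims <- c(2, 2, 2)
  X <- matrix(rnorm(40 * 8), 40); X[, 3] <- 7
  m <- rewnpls_init(dims, J = 1)
  b <- observation_block(X, rnorm(40), dims = dims)
  m <- update_normalization(m, b)
  expect_equal(m$scale_x[3], 1)
  nb <- prewnpls:::apply_normalization(m, b)
  expect_equal(nb$X[, 3], rep(0, 40))
})

test_that("covariance recursion is associative at mu1 = 1 and forgets at mu1 = 0", {
  set.seed(402)
  dims <- c(2, 3, 2); D <- prod(dims)
  X <- matrix(rnorm(80 * D), 80); Y <- matrix(rnorm(80 * 2), 80)
  b_all <- observation_block(X, Y, dims = dims)
  b1 <- observation_block(X[1:40, ], Y[1:40, ], dims = dims)
  b2 <- observation_block(X[41:80, ], Y[41:80, ], dims = dims)
  m1 <- update_covariances(rewnpls_init(dims, J = 2, normalize = FALSE), b_all)
  m2 <- rewnpls_init(dims, J = 2, normalize = FALSE)
  m2 <- update_covariances(update_covariances(m2, b1), b2)
  expect_equal(m1$XX, m2$XX, tolerance = 1e-10)
  expect_equal(m1$XY, m2$XY, tolerance = 1e-10)
  expect_equal(m2$UI, 2L)
  # single-sample block is a rank-1 update
  x <- rnorm(D); y <- rnorm(2)
  ms <- update_covariances(rewnpls_init(dims, J = 2),
                           observation_block(matrix(x, 1), matrix(y, 1),
                                             dims = dims))
  expect_equal(ms$XX, tcrossprod(x), tolerance = 1e-12)
  expect_equal(ms$XY, tcrossprod(x, y), tolerance = 1e-12)
  # mu1 = 0: full forgetting, state depends only on the latest block
  m0 <- rewnpls_init(dims, J = 2, normalize = FALSE)
  m0$mu1 <- 0
  m0 <- update_covariances(update_covariances(m0, b1), b2)
  expect_equal(m0$XX, crossprod(b2$X), tolerance = 1e-12)
})

test_that("penalization sets shrink by the nonzero projector coordinates", {
  s <- penalization_sets(c(2, 2, 4), penalized_modes = 3L)
  fac <- structure(list(w1 = c(1, 0), w2 = c(0, 1),
                        w3 = c(0.6, 0.8, 0, 0)), class = "projector_factor")
  s2 <- update_penalization_sets(s, fac)
  expect_equal(s2$sets[[3]], c(3L, 4L))
  # all-zero projector leaves the sets unchanged
  facz <- structure(list(w1 = c(0, 0), w2 = c(0, 0), w3 = numeric(4)),
                    class = "projector_factor")
  expect_equal(update_penalization_sets(s, facz)$sets[[3]], 1:4)
  # dense projector empties the set
  facd <- structure(list(w1 = c(1, 0), w2 = c(0, 1), w3 = rep(0.5, 4)),
                    class = "projector_factor")
  expect_equal(update_penalization_sets(s, facd)$sets[[3]], integer(0))
})

test_that("noiseless low-dimensional data is fit exactly with enough factors", {
  set.seed(403)
  dims <- c(3, 4, 8); D <- prod(dims); K <- 3; n <- 60
  coords <- sort(sample(D, K))
  Z <- matrix(rnorm(n * K), n, K)
  X <- matrix(0, n, D); X[, coords] <- Z
  alpha <- matrix(rnorm(K * 2), K, 2)
  Y <- Z %*% alpha + rep(c(0.3, -0.2), each = n)
  m <- fit_update(rewnpls_init(dims, J = 2, F = K),
                  observation_block(X, Y, dims = dims))
  expect_lt(max(abs(predict(m, X, f = K) - Y)), 1e-6)
})

test_that("unpenalized and lambda = 0 penalized fits are identical", {
  st <- make_stream()
  m1 <- rewnpls_init(c(3, 4, 8), J = 2, F = 4)
  m2 <- rewnpls_init(c(3, 4, 8), J = 2, F = 4)
  pc0 <- penalty_config(p = 1, lam_per_mode = c(0, 0, 0), penalized_modes = 3L)
  for (b in st$session$blocks) {
    m1 <- fit_update(m1, b)
    m2 <- fit_update(m2, b, pc0)
  }
  for (f in 1:4) {
    expect_equal(m1$beta[[f]], m2$beta[[f]], tolerance = 1e-12)
    expect_equal(m1$bias[[f]], m2$bias[[f]], tolerance = 1e-12)
  }
  expect_equal(m1$val_err, m2$val_err, tolerance = 1e-12)
})

test_that("channels absent from every projector have exactly-zero slices", {
  st <- make_stream(snr = 10)
  pc <- penalty_config(p = 0, lam_per_mode = c(0, 0, 0.05),
                       penalized_modes = 3L)
  m <- rewnpls_init(c(3, 4, 8), J = 2, F = 4)
  for (b in st$session$blocks) {
    m <- fit_update(m, b, pc)
    if (m$n_factors > 0) {
      used <- Reduce(`|`, lapply(m$factors, function(f) f$w3 != 0))
      excluded <- which(!used)
      for (f in seq_len(m$F)) {
        bt <- beta_tensor(m, f)
        if (length(excluded)) expect_true(all(bt[, , excluded, ] == 0))
      }
    }
  }
})

test_that("recursive validation selects the generating factor count", {
  set.seed(404)
  dims <- c(2, 2, 3); D <- prod(dims)
  m <- rewnpls_init(dims, J = 2, F = 3)
  # craft a family where member 2 generates the data exactly
  B2 <- matrix(rnorm(D * 2), D, 2)
  m$beta <- list(matrix(0, D, 2), B2, matrix(rnorm(D * 2), D, 2))
  m$bias <- list(numeric(2), c(0.1, -0.3), numeric(2))
  m$n_factors <- 3L; m$UI <- 1L
  X <- matrix(rnorm(50 * D), 50)
  Y <- X %*% B2 + rep(c(0.1, -0.3), each = 50)
  m <- recursive_validation(m, observation_block(X, Y, dims = dims))
  expect_equal(m$f_star, 2L)
  expect_equal(m$val_err[2], 0, tolerance = 1e-20)
  expect_true(all(is.finite(m$val_err)) && all(m$val_err >= 0))
  # identical errors across f resolve to the smallest member
  m2 <- rewnpls_init(dims, J = 2, F = 3)
  B <- matrix(rnorm(D * 2), D, 2)
  m2$beta <- list(B, B, B); m2$bias <- rep(list(numeric(2)), 3)
  m2$n_factors <- 3L; m2$UI <- 1L
  m2 <- recursive_validation(m2, observation_block(X, Y, dims = dims))
  expect_equal(m2$f_star, 1L)
})

test_that("fit_update accepts single-sample blocks and logs each update", {
  set.seed(405)
  dims <- c(2, 2, 2)
  m <- rewnpls_init(dims, J = 1, F = 2)
  for (i in 1:3) {
    b <- observation_block(matrix(rnorm(8), 1), matrix(rnorm(1), 1),
                           dims = dims)
    m <- fit_update(m, b)
  }
  expect_equal(m$UI, 3L)
  expect_length(m$log, 3L)
  expect_equal(m$log[[3]]$UI, 3L)
  expect_true(is.finite(m$log[[3]]$channel_sparsity))
})

test_that("prediction is the documented affine map in original units", {
  st <- make_stream()
  m <- rewnpls_init(c(3, 4, 8), J = 2, F = 3)
  for (b in st$session$blocks) m <- fit_update(m, b)
  b <- st$session$blocks[[1]]
  f <- m$f_star
  manual <- b$X %*% m$beta[[f]] + rep(m$bias[[f]], each = b$n)
  expect_equal(predict(m, b), manual, tolerance = 1e-12)
  # single-tensor and block interfaces agree
  x1 <- array(b$X[1, ], dim = c(3, 4, 8))
  expect_equal(predict(m, x1), predict(m, b)[1, , drop = FALSE],
               tolerance = 1e-12)
  expect_error(predict(m, b, f = 99), "out of range")
})
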