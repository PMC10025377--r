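# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (plain index loops, naive grids) so they
# can catch convention or wiring mistakes.

# Mode-wise unfolding by explicit index loops: row = mode index, column
# enumerates the complementary modes in increasing mode order, earlier mode
# fastest.
loop_unfold <- function(t, mode) {
  d <- dim(t)
  others <- setdiff(1:3, mode)
  out <- matrix(0, d[mode], prod(d[others]))
  for (i1 in seq_len(d[1])) for (i2 in seq_len(d[2])) for (i3 in seq_len(d[3])) {
    idx <- c(i1, i2, i3)
    col <- idx[others[1]] + (idx[others[2]] - 1L) * d[others[1]]
    out[idx[mode], col] <- t[i1, i2, i3]
  }
  out
}

# k-mode product by explicit loops (order-3 only, small dims).
loop_kmode <- function(t, m, mode) {
  d <- dim(t)
  nd <- d; nd[mode] <- nrow(m)
  out <- array(0, nd)
  for (a in seq_len(nd[1])) for (b in seq_len(nd[2])) for (cc in seq_len(nd[3])) {
    s <- 0
    for (k in seq_len(d[mode])) {
      idx <- c(a, b, cc); idx[mode] <- k
      row <- c(a, b, cc)[mode]
      s <- s + m[row, k] * t[idx[1], idx[2], idx[3]]
    }
    out[a, b, cc] <- s
  }
  out
}

# Two-stage grid minimizer of J(w) = gain (w - u)^2 + lam g_p(w): coarse scan
# over [-hw, hw], then a 1e-6-step scan around the coarse argmin (0 always
# included). Effective resolution 1e-6.
grid_min_J <- function(u, gain, lam, p, hw = 2 * max(1, abs(u))) {
  Jf <- function(w) {
    gp <- switch(as.character(p),
                 "0" = as.numeric(w != 0),
                 "0.5" = sqrt(abs(w)),
                 "1" = abs(w))
    gain * (w - u)^2 + lam * gp
  }
  coarse <- seq(-hw, hw, by = 1e-4)
  w0 <- coarse[which.min(Jf(coarse))]
  fine <- c(0, seq(w0 - 2e-4, w0 + 2e-4, by = 1e-6))
  J <- Jf(fine)
  best <- which(J <= min(J) + 1e-15)
  cand <- fine[best]
  cand[which.min(abs(cand))]
}

# Plain (unpenalized) rank-1 ALS with the same deterministic initialization
# convention, written independently with explicit Kronecker algebra.
plain_als_rank1 <- function(v, max_iter = 100, tol = 1e-6) {
  d <- dim(v)
  w <- lapply(1:3, function(m) {
    um <- loop_unfold(v, m)
    s <- svd(um, nu = 1, nv = 0)
    u1 <- as.numeric(s$u)
    if (u1[which.max(abs(u1))] < 0) -u1 else u1
  })
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (m in 1:3) {
      others <- setdiff(1:3, m)
      K <- kronecker(w[[others[2]]], w[[others[1]]])
      wt <- as.numeric(loop_unfold(v, m) %*% K) / sum(K^2)
      wt <- wt / sqrt(sum(wt^2))
      delta <- max(delta, sqrt(sum((wt - w[[m]])^2)))
      w[[m]] <- wt
    }
    if (delta < tol) break
  }
  for (m in 1:3) if (w[[m]][which.max(abs(w[[m]]))] < 0) w[[m]] <- -w[[m]]
  rho <- sum(v * outer(outer(w[[1]], w[[2]]), w[[3]]))
  list(w1 = w[[1]], w2 = w[[2]], w3 = w[[3]], rho = rho)
}

# Random order-3 tensor.
rand_tensor <- function(dims) array(rnorm(prod(dims)), dim = dims)

# Small synthetic stream shared by model-level tests.
make_stream <- function(dims = c(3, 4, 8), J = 2, n = 120, block = 20,
                        snr = 20, support = 4, rank_true = 2,
                        seed_gt = 5, seed_ses = 6) {
  gt <- make_ground_truth(dims, J = J, support_size = support,
                          rank_true = rank_true, snr = snr, seed = seed_gt)
  sp <- session_spec(n, block, dims, J = J, seed = seed_ses)
  list(gt = gt, session = simulate_session(gt, sp))
}
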