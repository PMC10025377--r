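#' Synthetic sessions with known sparse multilinear ground truth
#'
#' The generator emulates the statistical structure the decoder assumes:
#' targets are an affine function of a feature tensor through a channel-
#' sparse low-rank coefficient tensor, `y_t = <X_t, beta_true> + bias + eps`,
#' with features built from temporally smoothed (AR(1)) Gaussian noise plus
#' target-locked components, streamed in update blocks. It does not emulate
#' raw ECoG voltages, electrode geometry, or user adaptation.
#'
#' @name synthetic-data
NULL

#' Sparse multilinear ground-truth model
#'
#' `beta_true = sum_r g_r a_r o b_r o c_r o d_r` where every channel factor
#' `c_r` is supported on one common random channel subset `S` of size
#' `support_size`; channel slices outside `S` are exactly zero. Support
#' loadings are drawn with magnitudes in (0.5, 1.5) so that every informative
#' channel carries a non-negligible share of the signal.
#'
#' @param dims length-3 feature dims (I1, I2, I3 = channels).
#' @param J number of outputs.
#' @param support_size number of informative channels (<= I3).
#' @param rank_true number of rank-1 components (default 3).
#' @param snr target signal-to-noise variance ratio
#'   `var(<X, beta>) / var(eps)` used by [simulate_session()] (default 10).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `ground_truth` with `beta_true`
#'   (I1 x I2 x I3 x J array), `bias_true`, `support` (sorted channel
#'   indices), `rank_true`, `snr`, `dims`, `J`, `seed`.
#' @export
make_ground_truth <- function(dims, J = 3L, support_size, rank_true = 3L,
                              snr = 10, seed) {
  dims <- as.integer(dims)
  if (support_size > dims[3]) stop("`support_size` exceeds the channel count")
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(as.integer(seed))
  S <- sort(sample.int(dims[3], support_size))
  beta <- array(0, dim = c(dims, J))
  unit <- function(v) v / sqrt(sum(v^2))
  for (r in seq_len(rank_true)) {
    a <- unit(stats::rnorm(dims[1]))
    b <- unit(stats::rnorm(dims[2]))
    cc <- numeric(dims[3])
    cc[S] <- sample(c(-1, 1), support_size, replace = TRUE) *
      stats::runif(support_size, 0.5, 1.5)
    cc <- unit(cc)
    d <- unit(stats::rnorm(J))
    beta <- beta + outer(outer(outer(a, b), cc), d)
  }
  bias <- stats::rnorm(J, sd = 0.1)
  structure(list(beta_true = beta, bias_true = bias, support = S,
                 rank_true = as.integer(rank_true), snr = snr,
                 dims = dims, J = as.integer(J), seed = as.integer(seed)),
            class = "ground_truth")
}

#' Session specification
#'
#' @param n_samples total samples (must be a multiple of `block_size`).
#' @param block_size samples per update block (Delta L).
#' @param dims,J feature-tensor dims and output count.
#' @param seed mandatory integer seed.
#' @param target_switch_period samples between target switches (default 100).
#' @param ar_coef AR(1) coefficient of the feature noise (default 0.9,
#'   mimicking the autocorrelation of overlapping wavelet features).
#' @param target_gain amplitude of the target-locked feature component
#'   (default 1).
#' @return list of class `session_spec`.
#' @export
session_spec <- function(n_samples, block_size, dims, J = 3L, seed,
                         target_switch_period = 100L, ar_coef = 0.9,
                         target_gain = 1) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_samples %% block_size != 0)
    stop("`n_samples` must be a multiple of `block_size`")
  structure(list(n_samples = as.integer(n_samples),
                 block_size = as.integer(block_size),
                 dims = as.integer(dims), J = as.integer(J),
                 seed = as.integer(seed),
                 target_switch_period = as.integer(target_switch_period),
                 ar_coef = ar_coef, target_gain = target_gain),
            class = "session_spec")
}

# Lift a J-vector sequence into feature space so that <lift(y)_t, beta_j>
# reproduces y_t exactly: lift(y) = sum_k c_k(t) B_k with B_k the k-th output
# slice of beta_true and c = M^{-1} y, M the Gram matrix of the slices.
target_lift_basis <- function(gt) {
  D <- prod(gt$dims); J <- gt$J
  Bm <- matrix(gt$beta_true, D, J)
  M <- crossprod(Bm)
  # pseudo-inverse: when rank_true < J the output slices only span a
  # rank_true-dimensional subspace and the lift covers the representable
  # component of y
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  Minv <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  list(Bm = Bm, Minv = Minv)
}

#' Simulate one session as a sequence of observation blocks
#'
#' Features are `target_gain * lift(d_t) + AR(1) Gaussian noise`, where
#' `d_t` is the current unit target direction (switching every
#' `target_switch_period` samples) and the lift maps directions into feature
#' space along the ground-truth coefficient slices. Targets are then
#' computed as `y_t = <X_t, beta_true> + bias_true + eps_t` with the noise
#' sd set from the ground truth's `snr` (per output, from the realized
#' signal variance, so the empirical variance ratio matches the request).
#'
#' @param gt [make_ground_truth()] output.
#' @param spec [session_spec()].
#' @return list of class `session`: `blocks` (list of
#'   [observation_block()]), `gt_signal` (the noiseless `<X, beta> + bias`),
#'   `targets_dir` (the target directions), `sigma` (per-output noise sd),
#'   `spec`.
#' @export
simulate_session <- function(gt, spec) {
  stopifnot(inherits(gt, "ground_truth"), inherits(spec, "session_spec"))
  if (!all(spec$dims == gt$dims) || spec$J != gt$J)
    stop("session dims/J do not match the ground truth")
  set.seed(spec$seed)
  n <- spec$n_samples; D <- prod(gt$dims); J <- gt$J

  # piecewise-constant unit target directions
  nseg <- ceiling(n / spec$target_switch_period)
  dirs <- matrix(stats::rnorm(nseg * J), nseg, J)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  seg <- rep(seq_len(nseg), each = spec$target_switch_period)[seq_len(n)]
  Dirs <- dirs[seg, , drop = FALSE]

  lift <- target_lift_basis(gt)
  Xs <- spec$target_gain * (Dirs %*% lift$Minv) %*% t(lift$Bm)  # n x D signal

  # AR(1) feature noise with unit marginal variance
  eps <- matrix(stats::rnorm(n * D), n, D)
  noise <- matrix(0, n, D)
  a <- spec$ar_coef
  noise[1, ] <- eps[1, ]
  if (n > 1) for (t in 2:n) noise[t, ] <- a * noise[t - 1, ] + sqrt(1 - a^2) * eps[t, ]
  Xm <- Xs + noise

  sig <- Xm %*% lift$Bm                       # n x J, <X_t, beta_true>
  sig <- sweep(sig, 2, gt$bias_true, "+")
  v_sig <- apply(sweep(sig, 2, gt$bias_true), 2, stats::var)
  sigma <- if (is.finite(gt$snr)) sqrt(v_sig / gt$snr) else rep(0, J)
  Y <- sig + matrix(stats::rnorm(n * J), n, J) %*% diag(sigma, J)

  nb <- n %/% spec$block_size
  idx <- split(seq_len(n), rep(seq_len(nb), each = spec$block_size))
  blocks <- lapply(idx, function(i)
    observation_block(Xm[i, , drop = FALSE], Y[i, , drop = FALSE],
                      dims = gt$dims))
  names(blocks) <- NULL
  structure(list(blocks = blocks, gt_signal = sig, targets_dir = Dirs,
                 sigma = sigma, spec = spec),
            class = "session")
}

#' Closed-loop pursuit rollout with a decoder in the loop
#'
#' Emulates the 3D pursuit task at the 10-Hz command rate: at each step the
#' optimal output is the Cartesian vector from the current effector position
#' to the active target, features are generated from the ground truth
#' conditioned on that optimal output (plus feature noise), the decoder's
#' prediction moves the effector by `gain * yhat`, and targets switch every
#' `target_switch_period` steps. The position is never reset.
#'
#' @param gt [make_ground_truth()] output with `J = 3`.
#' @param decoder function mapping a feature tensor (I1 x I2 x I3) to a
#'   length-3 prediction.
#' @param spec [session_spec()] (`n_samples` = number of 10-Hz steps).
#' @param gain effector step gain kappa (default 0.05).
#' @param targets matrix of candidate target positions (default: the 8
#'   vertices of the unit cube centred at the origin).
#' @param noise_sd sd of the additive feature noise (default 0.1).
#' @return list of class `pursuit_rollout` with matrices `positions`,
#'   `targets`, `optimal` (y_t), `predicted` (yhat_t), and `undefined`
#'   (logical mask of steps where the optimal direction had zero norm).
#' @export
pursuit_rollout <- function(gt, decoder, spec, gain = 0.05,
                            targets = as.matrix(expand.grid(
                              c(-1, 1), c(-1, 1), c(-1, 1))),
                            noise_sd = 0.1) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gt$J != 3L) stop("pursuit rollout requires 3 Cartesian outputs")
  set.seed(spec$seed)
  n <- spec$n_samples
  lift <- target_lift_basis(gt)
  pos <- numeric(3)
  P <- matrix(0, n, 3); Tg <- matrix(0, n, 3)
  Yopt <- matrix(0, n, 3); Yhat <- matrix(0, n, 3)
  undef <- logical(n)
  tgt_idx <- sample.int(nrow(targets), 1L)
  for (t in seq_len(n)) {
    if (t > 1L && (t - 1L) %% spec$target_switch_period == 0L)
      tgt_idx <- sample.int(nrow(targets), 1L)
    tgt <- as.numeric(targets[tgt_idx, ])
    y <- tgt - pos
    undef[t] <- sqrt(sum(y^2)) == 0
    xv <- as.numeric(lift$Bm %*% (lift$Minv %*% (y - gt$bias_true))) +
      stats::rnorm(prod(gt$dims), sd = noise_sd)
    Xt <- array(xv, dim = gt$dims)
    yh <- as.numeric(decoder(Xt))
    pos <- pos + gain * yh
    P[t, ] <- pos; Tg[t, ] <- tgt; Yopt[t, ] <- y; Yhat[t, ] <- yh
  }
  structure(list(positions = P, targets = Tg, optimal = Yopt,
                 predicted = Yhat, undefined = undef),
            class = "pursuit_rollout")
}
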