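#' Rank-1 PARAFAC by (penalized) alternating least squares
#'
#' Approximates an order-3 tensor `V` by a single outer product
#' `rho * w1 o w2 o w3` with unit-norm mode vectors. ALS cycles the modes
#' 1 -> 2 -> 3; each mode update solves the mode's least-squares problem
#' coordinate-wise, optionally applying the exact Lp proximal operator to the
#' coordinates listed in the mode's penalization set, and then normalizes the
#' vector. Only one rank-1 step is ever used by the decoder (R = 1).
#'
#' @name parafac1
NULL

#' Unpenalized least-squares update of one mode
#'
#' With the other two projectors fixed, the mode-`mode` vector minimizing
#' `||unfold(v, mode) - w K^T||^2` is `unfold(v, mode) K / ||K||^2`, where
#' `K` is the Kronecker vector of the fixed projectors in the
#' unfold-consistent order.
#'
#' @param v order-3 array.
#' @param fixed list of the two fixed projector vectors, in increasing mode
#'   order (e.g. for `mode = 2`, `list(w1, w3)`).
#' @param mode mode being updated (1, 2 or 3).
#' @return the (un-normalized) least-squares vector, or all zeros with
#'   attribute `degenerate = TRUE` when `||K|| = 0`.
#' @export
ls_mode_update <- function(v, fixed, mode) {
  w <- rep(list(NULL), 3)
  w[setdiff(1:3, mode)] <- fixed
  K <- fixed_kron(w[[1]], w[[2]], w[[3]], mode)
  nk2 <- sum(K^2)
  if (nk2 == 0) {
    out <- numeric(dim(v)[mode])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(unfold(v, mode) %*% K) / nk2
}

#' Penalized least-squares update of one mode
#'
#' As [ls_mode_update()], but coordinates belonging to the mode's
#' penalization set are replaced by the exact Lp minimizer
#' [scalar_penalized_ls()] with `gain = ||K||^2` and the mode's lambda.
#' The returned vector is *not* normalized.
#'
#' @inheritParams ls_mode_update
#' @param pc [penalty_config()].
#' @param sets [penalization_sets()].
#' @return numeric vector (possibly with zeros), attribute `degenerate` as in
#'   [ls_mode_update()].
#' @export
penalized_mode_update <- function(v, fixed, mode, pc, sets) {
  w <- rep(list(NULL), 3)
  w[setdiff(1:3, mode)] <- fixed
  K <- fixed_kron(w[[1]], w[[2]], w[[3]], mode)
  nk2 <- sum(K^2)
  if (nk2 == 0) {
    out <- numeric(dim(v)[mode])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  u <- as.numeric(unfold(v, mode) %*% K) / nk2
  lam <- pc$lam_per_mode[mode]
  idx <- sets$sets[[mode]]
  if (lam > 0 && length(idx)) {
    u[idx] <- vapply(u[idx], scalar_penalized_ls, numeric(1),
                     gain = nk2, lam = lam, p = pc$p)
  }
  u
}

#' Rank-1 PARAFAC via alternating least squares
#'
#' @param v order-3 array to decompose.
#' @param pc [penalty_config()]; the default is unpenalized.
#' @param sets [penalization_sets()]; defaults to the full sets implied by
#'   `pc$penalized_modes`.
#' @param max_iter maximum number of mode sweeps (default 100).
#' @param tol convergence tolerance on the maximum projector change between
#'   sweeps (default 1e-6).
#' @param seed reserved for the randomized initialization fallback; the
#'   default initialization (leading left singular vector of each unfolding)
#'   is deterministic.
#' @return list of class `projector_factor` with elements `w1`, `w2`, `w3`
#'   (unit-norm, sign fixed so each factor's largest-magnitude entry is
#'   positive), `rho` (the scale `<v, w1 o w2 o w3>`), `iterations`, and
#'   `degenerate` (`TRUE` when a mode update collapsed to the zero vector,
#'   in which case the factors are all-zero).
#' @export
parafac1_als <- function(v, pc = penalty_config(),
                         sets = penalization_sets(dim(v), pc$penalized_modes),
                         max_iter = 100L, tol = 1e-6, seed = NULL) {
  d <- dim(v)
  if (is.null(d) || length(d) != 3L) stop("`v` must be an order-3 array")
  if (!all(is.finite(v))) stop("`v` must be finite")
  degen_out <- function(it) structure(
    list(w1 = numeric(d[1]), w2 = numeric(d[2]), w3 = numeric(d[3]),
         rho = 0, iterations = it, degenerate = TRUE),
    class = "projector_factor")
  if (all(v == 0)) return(degen_out(0L))

  # deterministic init: leading left singular vector of each unfolding
  w <- lapply(1:3, function(m) {
    s <- svd(unfold(v, m), nu = 1L, nv = 0L)
    fix_sign(as.numeric(s$u))
  })

  it <- 0L
  repeat {
    it <- it + 1L
    delta <- 0
    for (m in 1:3) {
      wt <- penalized_mode_update(v, w[setdiff(1:3, m)], m, pc, sets)
      if (isTRUE(attr(wt, "degenerate")) || all(wt == 0)) return(degen_out(it))
      wt <- wt / sqrt(sum(wt^2))
      delta <- max(delta, sqrt(sum((wt - w[[m]])^2)))
      w[[m]] <- wt
    }
    if (delta < tol || it >= max_iter) break
  }

  # sign convention: each factor's largest-|entry| positive; compensate in rho
  sgn <- 1
  for (m in 1:3) {
    i <- which.max(abs(w[[m]]))
    if (w[[m]][i] < 0) { w[[m]] <- -w[[m]]; sgn <- -sgn }
  }
  rho <- sum(v * outer(outer(w[[1]], w[[2]]), w[[3]]))
  structure(list(w1 = w[[1]], w2 = w[[2]], w3 = w[[3]], rho = rho,
                 iterations = it, degenerate = FALSE),
            class = "projector_factor")
}
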