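#' Exact scalar proximal operators for Lp-penalized least squares
#'
#' Each coordinate update of the penalized rank-1 PARAFAC step solves the
#' scalar problem
#' \deqn{\min_w \; J(w) = a (w - u)^2 + \lambda\, g_p(w)}
#' where `u` is the unpenalized least-squares value of the coordinate,
#' `a > 0` is the squared norm of the Kronecker vector of the fixed-mode
#' projectors, and `g_p` is the Lp penalty on a single coordinate:
#' `g_0(w) = 1{w != 0}`, `g_1(w) = |w|`, `g_{1/2}(w) = sqrt(|w|)`.
#'
#' Closed-form global minimizers (exact minimizers of the cost, ties between
#' a zero and a nonzero candidate resolve to zero, favouring sparsity):
#' \itemize{
#'   \item `p = 1`: soft thresholding,
#'     `w* = sign(u) * max(0, |u| - lambda / (2 a))`.
#'   \item `p = 0`: hard thresholding, `w* = u` if `a u^2 > lambda`, else 0.
#'   \item `p = 0.5`: half thresholding. `w* = 0` when
#'     `|u| <= (3/4) (lambda / a)^{2/3}`; otherwise the candidate is
#'     `sign(u) * B * |u|` with `B` the largest root in `[0, 1]` of
#'     `x (1 - x)^2 = C`, `C = lambda^2 / (16 a^2 |u|^3)`, kept only if it
#'     beats `J(0)`.
#' }
#'
#' @name penalty-prox
NULL

#' Scalar penalized least-squares minimizer
#'
#' @param u_ls unpenalized least-squares value of the coordinate.
#' @param gain positive quadratic gain (squared Kronecker-vector norm).
#' @param lam nonnegative penalization parameter.
#' @param p penalty exponent: one of 0, 0.5, 1.
#' @return the global minimizer of `J(w)` (a single number).
#' @seealso [scalar_penalized_ls_oracle()] for the brute-force check,
#'   [cubic_largest_root()] for the half-thresholding cubic.
#' @export
scalar_penalized_ls <- function(u_ls, gain, lam, p) {
  if (!is.finite(u_ls)) stop("`u_ls` must be finite")
  if (!is.finite(gain) || gain <= 0) stop("`gain` must be > 0")
  if (!is.finite(lam) || lam < 0) stop("`lam` must be >= 0")
  if (!(p %in% c(0, 0.5, 1))) stop("`p` must be 0, 0.5 or 1")
  if (lam == 0) return(u_ls)
  u <- u_ls
  if (p == 1) {
    thr <- lam / (2 * gain)
    return(sign(u) * max(0, abs(u) - thr))
  }
  if (p == 0) {
    # J(u) = lam vs J(0) = gain * u^2; tie -> 0
    return(if (gain * u^2 > lam) u else 0)
  }
  # p == 0.5
  thr <- 0.75 * (lam / gain)^(2 / 3)
  if (abs(u) <= thr) return(0)
  C <- lam^2 / (16 * gain^2 * abs(u)^3)
  if (C > 4 / 27) return(0)          # no admissible root (cannot occur past thr)
  B <- cubic_largest_root(C)
  w <- sign(u) * B * abs(u)
  j0 <- gain * u^2
  jw <- gain * (w - u)^2 + lam * sqrt(abs(w))
  if (jw < j0) w else 0
}

#' Largest root of x (1 - x)^2 = C in [0, 1]
#'
#' The map `x (1 - x)^2` increases from 0 at `x = 0` to its maximum `4/27`
#' at `x = 1/3` and decreases back to 0 at `x = 1`, so for
#' `0 <= C <= 4/27` the largest root lies in `[1/3, 1]`. Solved by bisection
#' (unconditionally stable, no complex arithmetic) to absolute tolerance
#' 1e-12.
#'
#' @param C nonnegative value, at most `4/27`.
#' @return the largest root in `[0, 1]`.
#' @export
cubic_largest_root <- function(C) {
  if (!is.finite(C) || C < 0) stop("`C` must be nonnegative")
  if (C > 4 / 27 + 1e-15) stop("no root: C exceeds 4/27")
  C <- min(C, 4 / 27)
  f <- function(x) x * (1 - x)^2 - C
  lo <- 1 / 3; hi <- 1
  # f(lo) >= 0 >= f(hi)
  while (hi - lo > 1e-13) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Brute-force grid oracle for the scalar penalized problem
#'
#' Minimizes `J(w)` over an equally spaced grid on
#' `[-halfwidth, halfwidth]` (always including `w = 0` exactly). Intended for
#' tests only; the closed forms in [scalar_penalized_ls()] are the
#' implementation.
#'
#' @inheritParams scalar_penalized_ls
#' @param halfwidth half-width of the search interval.
#' @param step grid spacing (> 0).
#' @return the grid minimizer.
#' @export
scalar_penalized_ls_oracle <- function(u_ls, gain, lam, p,
                                       halfwidth = 2 * max(1, abs(u_ls)),
                                       step = 1e-6) {
  if (step <= 0) stop("`step` must be > 0")
  grid <- seq(-halfwidth, halfwidth, by = step)
  if (!any(grid == 0)) grid <- sort(c(grid, 0))
  gp <- switch(as.character(p),
               "0"   = as.numeric(grid != 0),
               "0.5" = sqrt(abs(grid)),
               "1"   = abs(grid),
               stop("`p` must be 0, 0.5 or 1"))
  J <- gain * (grid - u_ls)^2 + lam * gp
  # ties resolve toward 0 to mirror the closed form's sparsity preference
  best <- which(J <= min(J) + 1e-15)
  cand <- grid[best]
  cand[which.min(abs(cand))]
}

#' Penalty configuration for PREW-NPLS
#'
#' @param p penalty exponent (0, 0.5 or 1).
#' @param lam_per_mode numeric length-3 vector of penalization parameters
#'   `lambda_i in [0, 1]` per tensor mode; modes not in `penalized_modes`
#'   must be (and are forced to) 0.
#' @param penalized_modes integer subset of 1:3 (default: modes with
#'   `lambda > 0`).
#' @return list of class `penalty_config`.
#' @export
penalty_config <- function(p = 0, lam_per_mode = c(0, 0, 0),
                           penalized_modes = which(lam_per_mode > 0)) {
  if (!(p %in% c(0, 0.5, 1))) stop("`p` must be 0, 0.5 or 1")
  lam <- as.numeric(lam_per_mode)
  if (length(lam) != 3L || any(!is.finite(lam)) || any(lam < 0) || any(lam > 1))
    stop("`lam_per_mode` must be 3 values in [0, 1]")
  penalized_modes <- as.integer(penalized_modes)
  if (!all(penalized_modes %in% 1:3)) stop("`penalized_modes` must be in 1:3")
  lam[setdiff(1:3, penalized_modes)] <- 0
  structure(list(p = p, lam_per_mode = lam,
                 penalized_modes = sort(penalized_modes)),
            class = "penalty_config")
}

#' Initial (full) penalization sets
#'
#' At the first factor of a model update every coordinate of a penalized
#' mode is eligible for penalization; the sets then shrink across factors
#' (see [update_penalization_sets()]).
#'
#' @param dims length-3 mode dimensions.
#' @param penalized_modes integer subset of 1:3.
#' @return list of class `penalization_sets`: one integer vector per mode.
#' @export
penalization_sets <- function(dims, penalized_modes = integer(0)) {
  dims <- as.integer(dims)
  sets <- lapply(1:3, function(m)
    if (m %in% penalized_modes) seq_len(dims[m]) else integer(0))
  structure(list(sets = sets, dims = dims), class = "penalization_sets")
}
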