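#' Recursive exponentially weighted N-way PLS decoder
#'
#' The decoder maintains, across streamed update blocks, the covariance
#' matrices `XX` (D x D, D = I1*I2*I3) and `XY` (D x J) of the unfolded
#' feature tensors and targets, together with exponentially weighted
#' normalization statistics, using a common forgetting factor `mu1`:
#' `XX <- mu1 * XX + Xn' Xn`, `XY <- mu1 * XY + Xn' Yn`.
#'
#' At every update a family of models with 1..F latent factors is
#' re-extracted from the covariances by a kernel-PLS recursion: for each
#' factor the (deflated) cross-covariance is collapsed to an order-3 tensor
#' `V`, a rank-1 PARAFAC with optional Lp penalization supplies the mode
#' projectors, and loadings / regression coefficients are accumulated with
#' XY-only deflation. `V` is scaled to unit Frobenius norm before each
#' rank-1 extraction; only the unit-norm factors are used downstream, so the
#' scaling leaves the unpenalized algorithm unchanged while giving the
#' penalization parameter `lambda` a stable O(1) scale across updates and
#' factors.
#'
#' The number of factors actually used for prediction, `f_star`, is chosen by
#' a recursive validation loop: each incoming block is scored against the
#' *previous* model family before being absorbed, and per-factor validation
#' errors are accumulated with the same forgetting factor.
#'
#' Penalization sets are reset to full at the start of every update
#' iteration; within one update they shrink across factors, so a coordinate
#' selected (nonzero) at factor f is no longer penalized at factors > f.
#' Channels zeroed at one update may therefore re-enter at the next.
#'
#' @name rewnpls
NULL

#' Bundle one update block of observations
#'
#' @param X order-4 array (`n` samples x I1 x I2 x I3), or an `n x D` matrix
#'   already unfolded in native (mode-1-fastest) order.
#' @param Y numeric matrix (`n` x J) of targets (a vector is treated as one
#'   column).
#' @param dims mode dimensions, required when `X` is a matrix.
#' @return list of class `observation_block` with elements `X` (n x D
#'   matrix), `Y`, `n`, `dims`.
#' @export
observation_block <- function(X, Y, dims = NULL) {
  if (is.matrix(X) && !is.null(dims)) {
    dims <- as.integer(dims)
    if (ncol(X) != prod(dims)) stop("ncol(X) must equal prod(dims)")
    Xm <- X
  } else {
    d <- dim(X)
    if (is.null(d) || length(d) != 4L)
      stop("`X` must be an order-4 array (samples x I1 x I2 x I3)")
    dims <- d[-1]
    Xm <- matrix(X, nrow = d[1])
  }
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(Xm)) stop("X and Y must have the same sample count")
  if (!all(is.finite(Xm)) || !all(is.finite(Y)))
    stop("observations must be finite")
  structure(list(X = Xm, Y = Y, n = nrow(Xm), dims = dims),
            class = "observation_block")
}

#' Initialize a REW-NPLS / PREW-NPLS decoder
#'
#' The decoder starts from the zero model: predictions before the first
#' update are the zero vector.
#'
#' @param dims length-3 feature-tensor dimensions (time-lag, frequency,
#'   channel); the default matches 1-s epochs at 586 Hz with 15 wavelet
#'   bands on 64 electrodes.
#' @param J number of outputs (3 for a Cartesian velocity command).
#' @param F upper bound on the latent-space dimension (default 100).
#' @param mu1 forgetting factor in (0, 1]; 1 = no forgetting (default).
#' @param normalize center/scale features and center targets with
#'   exponentially weighted running statistics (default TRUE).
#' @param als_max_iter,als_tol ALS controls passed to [parafac1_als()].
#' @return object of class `rewnpls`.
#' @export
rewnpls_init <- function(dims = c(10L, 15L, 64L), J = 3L, F = 100L, mu1 = 1,
                         normalize = TRUE, als_max_iter = 100L,
                         als_tol = 1e-6) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  if (!(is.numeric(mu1) && length(mu1) == 1L && mu1 > 0 && mu1 <= 1))
    stop("`mu1` must be in (0, 1]")
  F <- as.integer(F)
  if (F < 1L) stop("`F` must be >= 1")
  D <- prod(dims)
  structure(list(
    dims = dims, J = as.integer(J), F = F, mu1 = mu1,
    normalize = isTRUE(normalize),
    als_max_iter = als_max_iter, als_tol = als_tol,
    # normalization statistics (exponentially weighted sums)
    sw = 0, sx = numeric(D), sxx = numeric(D), sy = numeric(J),
    mean_x = numeric(D), scale_x = rep(1, D), mean_y = numeric(J),
    # covariances
    XX = NULL, XY = NULL, UI = 0L,
    # model family
    beta = vector("list", F), bias = vector("list", F),
    factors = list(), n_factors = 0L,
    val_err = numeric(F), f_star = 1L,
    log = list()
  ), class = "rewnpls")
}

#' Update the running normalization statistics
#'
#' Exponentially weighted (factor `mu1`) running mean and standard deviation
#' of every feature coordinate and running mean of every output. Coordinates
#' with (near-)zero variance get their scale clamped to 1.
#'
#' @param model `rewnpls` object.
#' @param block [observation_block()].
#' @return the updated model.
#' @export
update_normalization <- function(model, block) {
  stopifnot(inherits(model, "rewnpls"), inherits(block, "observation_block"))
  if (!model$normalize) return(model)
  mu <- model$mu1
  model$sw <- mu * model$sw + block$n
  model$sx <- mu * model$sx + colSums(block$X)
  model$sxx <- mu * model$sxx + colSums(block$X^2)
  model$sy <- mu * model$sy + colSums(block$Y)
  model$mean_x <- model$sx / model$sw
  v <- model$sxx / model$sw - model$mean_x^2
  v[v < 0] <- 0
  scl <- sqrt(v)
  scl[scl <= 1e-12] <- 1          # zero-variance clamp
  model$scale_x <- scl
  model$mean_y <- model$sy / model$sw
  model
}

# Center/scale a block with the model's current statistics.
apply_normalization <- function(model, block) {
  if (!model$normalize) return(block)
  block$X <- sweep(sweep(block$X, 2, model$mean_x), 2, model$scale_x, "/")
  block$Y <- sweep(block$Y, 2, model$mean_y)
  block
}

#' Recursive covariance update
#'
#' `XX <- mu1 * XX + X'X`, `XY <- mu1 * XY + X'Y` on the (already
#' normalized) block; increments the update counter `UI`.
#'
#' @param model `rewnpls` object.
#' @param block normalized [observation_block()].
#' @return the updated model.
#' @export
update_covariances <- function(model, block) {
  stopifnot(inherits(model, "rewnpls"), inherits(block, "observation_block"))
  D <- prod(model$dims)
  if (ncol(block$X) != D || ncol(block$Y) != model$J)
    stop("block dimensions do not match the model")
  if (is.null(model$XX)) {
    model$XX <- matrix(0, D, D)
    model$XY <- matrix(0, D, model$J)
  }
  mu <- model$mu1
  if (mu != 1) {                 # avoid a D x D temporary when mu1 = 1
    model$XX <- mu * model$XX
    model$XY <- mu * model$XY
  }
  model$XX <- model$XX + crossprod(block$X)
  model$XY <- model$XY + crossprod(block$X, block$Y)
  model$UI <- model$UI + 1L
  model
}

#' Shrink penalization sets after one factor extraction
#'
#' Coordinates with nonzero projector entries correspond to tensor slices
#' already included in the model; they are removed from the sets of indices
#' eligible for penalization at later factors.
#'
#' @param sets [penalization_sets()].
#' @param factors `projector_factor` from [parafac1_als()].
#' @return the shrunken sets (always a subset of the input).
#' @export
update_penalization_sets <- function(sets, factors) {
  w <- list(factors$w1, factors$w2, factors$w3)
  for (m in 1:3) {
    if (length(sets$sets[[m]]))
      sets$sets[[m]] <- setdiff(sets$sets[[m]], which(w[[m]] != 0))
  }
  sets
}

#' Extract the model family from the current covariances
#'
#' Runs the (penalized) kernel-PLS factor loop on the stored `XX`/`XY`:
#' for each factor f the deflated cross-covariance is collapsed to an
#' order-3 tensor (via its leading output eigenvector when J > 1), scaled to
#' unit Frobenius norm, decomposed by [parafac1_als()] under the current
#' penalization sets, and the regression coefficients for the family member
#' with f factors are accumulated. Extraction truncates early when a factor
#' degenerates (zero projector or negligible explained covariance); later
#' family slots then repeat the last valid model so the family stays
#' F-indexed.
#'
#' @param model `rewnpls` object with `UI >= 1`.
#' @param pc [penalty_config()].
#' @param F number of family members to extract (default `model$F`).
#' @return the model with `beta`, `bias`, `factors`, `n_factors` refreshed.
#'   `beta[[f]]` is a `D x J` matrix in original feature/target units;
#'   [beta_tensor()] reshapes it to I1 x I2 x I3 x J.
#' @export
extract_model_family <- function(model, pc = penalty_config(), F = model$F) {
  stopifnot(inherits(model, "rewnpls"))
  if (model$UI < 1L) stop("no data absorbed yet: call fit_update first")
  dims <- model$dims; D <- prod(dims); J <- model$J
  XYw <- model$XY
  sets <- penalization_sets(dims, pc$penalized_modes)
  trXX <- sum(diag(model$XX))
  inv_scale <- 1 / model$scale_x

  pv <- list(); rv <- list(); facs <- list()
  Bacc <- matrix(0, D, J)
  beta <- vector("list", F); bias <- vector("list", F)
  nf <- 0L

  for (f in seq_len(F)) {
    if (J > 1L) {
      e <- leading_eigenvector(crossprod(XYw))
      Vvec <- as.numeric(XYw %*% e)
    } else {
      Vvec <- as.numeric(XYw)
    }
    nv <- sqrt(sum(Vvec^2))
    if (!is.finite(nv) || nv <= 1e-14) break
    V <- array(Vvec / nv, dim = dims)
    fac <- parafac1_als(V, pc, sets, max_iter = model$als_max_iter,
                        tol = model$als_tol)
    if (fac$degenerate) break
    w_vec <- as.numeric(outer(outer(fac$w1, fac$w2), fac$w3))
    # r maps the *original* (undeflated) features to this factor's score,
    # so the loadings and the deflation must use r, not w
    r_f <- w_vec
    for (k in seq_len(f - 1L))
      r_f <- r_f - sum(pv[[k]] * w_vec) * rv[[k]]
    xr <- as.numeric(model$XX %*% r_f)
    denom <- sum(r_f * xr)
    if (!is.finite(denom) || denom <= 1e-12 * trXX) break
    p_f <- xr / denom
    q_f <- as.numeric(crossprod(XYw, r_f)) / denom
    XYw <- XYw - denom * tcrossprod(p_f, q_f)
    Bacc <- Bacc + tcrossprod(r_f, q_f)

    pv[[f]] <- p_f; rv[[f]] <- r_f; facs[[f]] <- fac
    beta_orig <- Bacc * inv_scale            # rowwise de-scaling, zeros kept
    beta[[f]] <- beta_orig
    bias[[f]] <- model$mean_y - as.numeric(crossprod(beta_orig, model$mean_x))
    nf <- f
    sets <- update_penalization_sets(sets, fac)
  }

  if (nf < F) {
    fill_b <- if (nf > 0L) beta[[nf]] else matrix(0, D, J)
    fill_i <- if (nf > 0L) bias[[nf]] else numeric(J)
    for (f in seq.int(nf + 1L, F)) { beta[[f]] <- fill_b; bias[[f]] <- fill_i }
  }
  model$beta <- beta; model$bias <- bias
  model$factors <- facs; model$n_factors <- nf
  model
}

#' Score a new block against the previous model family
#'
#' For each family member f, the exponentially weighted validation loss is
#' updated with the block's mean squared prediction error:
#' `val_err_f <- mu1 * val_err_f + mse_f`. `f_star` is the argmin (ties
#' resolve to the smallest f). Called on raw blocks *before* they are
#' absorbed into the covariances, so validation data is always unseen.
#'
#' @param model `rewnpls` object.
#' @param block raw [observation_block()].
#' @return the model with `val_err` and `f_star` updated.
#' @export
recursive_validation <- function(model, block) {
  stopifnot(inherits(model, "rewnpls"), inherits(block, "observation_block"))
  if (model$UI < 1L || model$n_factors < 1L) {
    model$f_star <- 1L
    return(model)
  }
  mse <- vapply(seq_len(model$F), function(f) {
    Yh <- block$X %*% model$beta[[f]]
    Yh <- sweep(Yh, 2, model$bias[[f]], "+")
    mean((block$Y - Yh)^2)
  }, numeric(1))
  model$val_err <- model$mu1 * model$val_err + mse
  model$f_star <- which.min(model$val_err)   # ties -> smallest f
  model
}

#' One full decoder update iteration
#'
#' Orchestrates, for an incoming block: recursive validation against the
#' previous family, normalization-statistics update, covariance update, and
#' model-family re-extraction. Appends a structured log record (update
#' counter, `f_star`, channel sparsity, validation errors).
#'
#' @param model `rewnpls` object.
#' @param block [observation_block()] (`n >= 1`; single-sample blocks are
#'   accepted).
#' @param pc [penalty_config()]; the all-zero default reproduces the generic
#'   unpenalized algorithm.
#' @return the updated model.
#' @export
fit_update <- function(model, block, pc = penalty_config()) {
  stopifnot(inherits(model, "rewnpls"), inherits(block, "observation_block"))
  model <- recursive_validation(model, block)
  model <- update_normalization(model, block)
  nb <- apply_normalization(model, block)
  model <- update_covariances(model, nb)
  model <- extract_model_family(model, pc)
  sp <- sparsity_index(beta_tensor(model, model$f_star), mode = 3)
  model$log[[length(model$log) + 1L]] <- list(
    UI = model$UI, f_star = model$f_star, n_factors = model$n_factors,
    channel_sparsity = sp$percent_zero_slices,
    val_err = model$val_err)
  model
}

#' Regression coefficients of one family member as an order-4 tensor
#'
#' @param model fitted `rewnpls` object.
#' @param f family member (defaults to the selected `f_star`).
#' @return array I1 x I2 x I3 x J (original units).
#' @export
beta_tensor <- function(model, f = model$f_star) {
  stopifnot(inherits(model, "rewnpls"))
  if (f < 1L || f > model$F) stop("`f` out of range")
  B <- model$beta[[f]]
  if (is.null(B)) B <- matrix(0, prod(model$dims), model$J)
  array(B, dim = c(model$dims, model$J))
}

#' Predict from a fitted decoder
#'
#' Returns `<X, Beta_f> + bias_f` in original target units. Before any
#' update (or when extraction degenerated immediately) the zero model is
#' used and predictions are zero.
#'
#' @param object `rewnpls` object.
#' @param X a single feature tensor (I1 x I2 x I3), an order-4 block, an
#'   `n x D` matrix, or an [observation_block()].
#' @param f family member to use (default `f_star`).
#' @param ... unused.
#' @return `n x J` matrix of predictions.
#' @export
predict.rewnpls <- function(object, X, f = object$f_star, ...) {
  model <- object
  if (f < 1L || f > model$F) stop("`f` out of range (1..F)")
  D <- prod(model$dims)
  if (inherits(X, "observation_block")) {
    Xm <- X$X
  } else if (is.matrix(X) && ncol(X) == D) {
    Xm <- X
  } else {
    d <- dim(X)
    if (is.null(d)) stop("`X` must be an array or matrix")
    if (length(d) == 3L) Xm <- matrix(as.numeric(X), 1L, D)
    else if (length(d) == 4L) Xm <- matrix(X, nrow = d[1])
    else stop("`X` must be order 3 or 4")
  }
  if (ncol(Xm) != D) stop("feature dimension mismatch")
  if (model$UI < 1L || model$n_factors < 1L || is.null(model$beta[[f]]))
    return(matrix(0, nrow(Xm), model$J))
  Yh <- Xm %*% model$beta[[f]]
  sweep(Yh, 2, model$bias[[f]], "+")
}

#' @export
print.rewnpls <- function(x, ...) {
  cat("REW-NPLS decoder\n")
  cat("  feature dims:", paste(x$dims, collapse = " x "),
      " outputs:", x$J, "\n")
  cat("  F =", x$F, " mu1 =", x$mu1, " updates absorbed:", x$UI, "\n")
  if (x$UI > 0L)
    cat("  factors extracted:", x$n_factors, " selected f* =", x$f_star, "\n")
  invisible(x)
}
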