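#' Mode-wise tensor algebra
#'
#' Low-level operations on order-3 (and, where needed, order-4) numeric
#' arrays: mode-wise unfolding and folding, Kronecker chains, rank-1 outer
#' products, k-mode products and leading eigenvectors. All other modules are
#' built on these primitives.
#'
#' Column-ordering convention: `unfold(t, m)` puts mode `m` on the rows; the
#' columns enumerate the complementary modes in increasing mode order with the
#' *earlier* mode varying fastest. For mode 1 of an `I1 x I2 x I3` array this
#' is the native column-major layout, so column `k` corresponds to
#' `(i2, i3)` with `k = i2 + (i3 - 1) * I2`. Consistently,
#' `kron_chain(list(a, b))` places the *last* argument fastest
#' (`kronecker(a, b)`), so the Kronecker vector matching the mode-1 unfolding
#' is `kron_chain(list(w3, w2))`.
#'
#' @name tensor-ops
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an order-3 tensor
#'
#' @param data numeric vector or array with `prod(dims)` finite entries.
#' @param dims integer vector of length 3 (positive).
#' @param mode_names optional character vector of length 3; defaults to
#'   `c("time_lag", "frequency", "channel")`.
#' @return numeric array of class `tensor3`.
#' @export
tensor3 <- function(data, dims = dim(data),
                    mode_names = c("time_lag", "frequency", "channel")) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be 3 positive integers")
  if (length(data) != prod(dims))
    stop("length of `data` does not match prod(dims)")
  if (!all(is.finite(data)))
    stop("tensor entries must be finite")
  x <- array(as.numeric(data), dim = dims)
  attr(x, "mode_names") <- mode_names
  class(x) <- c("tensor3", class(x))
  x
}

as_tensor3 <- function(x) {
  if (inherits(x, "tensor3")) return(x)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected an order-3 array")
  tensor3(x, dim(x))
}

#' Unfold a tensor along one mode
#'
#' Row `j` of the result is the mode-`mode` slice `j` flattened so that the
#' column index matches [kron_chain()] applied to the complementary mode
#' vectors in *decreasing* mode order (see the convention in
#' [tensor-ops]).
#'
#' @param t order-3 array.
#' @param mode integer in 1:3.
#' @return matrix with attributes `source_mode` and `source_dims`, class
#'   `unfolded_matrix`.
#' @export
unfold <- function(t, mode) {
  d <- dim(t)
  if (is.null(d) || length(d) != 3L) stop("`t` must be an order-3 array")
  if (!(length(mode) == 1L && mode %in% 1:3))
    stop("`mode` must be 1, 2 or 3")
  perm <- c(mode, setdiff(1:3, mode))
  m <- matrix(aperm(unclass(t), perm), nrow = d[mode])
  attr(m, "source_mode") <- as.integer(mode)
  attr(m, "source_dims") <- d
  class(m) <- c("unfolded_matrix", class(m))
  m
}

#' Fold an unfolded matrix back to its source tensor
#'
#' Exact inverse of [unfold()]. The matrix must carry `source_mode` and
#' `source_dims` attributes (set by `unfold`, or supplied explicitly).
#'
#' @param m matrix as produced by [unfold()].
#' @param mode,dims override the stored source mode / dims.
#' @return the order-3 array (class `tensor3`).
#' @export
fold <- function(m, mode = attr(m, "source_mode"), dims = attr(m, "source_dims")) {
  if (is.null(mode) || is.null(dims))
    stop("`m` must carry source_mode/source_dims (or pass them explicitly)")
  dims <- as.integer(dims)
  if (nrow(m) != dims[mode] || ncol(m) != prod(dims[-mode]))
    stop("matrix shape does not match the declared source dims")
  perm <- c(mode, setdiff(1:3, mode))
  a <- array(as.numeric(m), dim = dims[perm])
  tensor3(aperm(a, order(perm)), dims)
}

#' Kronecker product of an ordered list of vectors
#'
#' `kron_chain(list(a, b))[k]` has the last argument varying fastest
#' (`a[i] * b[j]` at `k = (i - 1) * length(b) + j`), matching the unfolding
#' column convention when the complementary modes are listed in decreasing
#' order.
#'
#' @param vectors non-empty list of finite numeric vectors.
#' @return numeric vector of length `prod(lengths(vectors))`.
#' @export
kron_chain <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L)
    stop("`vectors` must be a non-empty list")
  if (!all(vapply(vectors, function(v) all(is.finite(v)), logical(1))))
    stop("all vectors must be finite")
  as.numeric(Reduce(kronecker, lapply(vectors, as.numeric)))
}

#' Rank-1 outer product of three vectors
#'
#' Entry `(i, j, k)` of the result is `w1[i] * w2[j] * w3[k]`.
#'
#' @param vectors list of 3 finite numeric vectors.
#' @return order-3 array (class `tensor3`).
#' @export
outer_rank1 <- function(vectors) {
  if (length(vectors) != 3L) stop("need exactly 3 vectors")
  w1 <- as.numeric(vectors[[1]]); w2 <- as.numeric(vectors[[2]])
  w3 <- as.numeric(vectors[[3]])
  if (!all(is.finite(c(w1, w2, w3)))) stop("vectors must be finite")
  tensor3(outer(outer(w1, w2), w3),
          c(length(w1), length(w2), length(w3)))
}

#' k-mode product of a tensor with a matrix
#'
#' Contracts mode `mode` of `t` (any order) with the columns of `m`:
#' the result has the mode-`mode` dimension replaced by `nrow(m)`.
#'
#' @param t numeric array of any order.
#' @param m matrix with `ncol(m) == dim(t)[mode]`.
#' @param mode integer mode to contract.
#' @return numeric array.
#' @export
kmode_product <- function(t, m, mode) {
  d <- dim(t)
  if (is.null(d)) stop("`t` must be an array")
  nord <- length(d)
  if (!(length(mode) == 1L && mode >= 1L && mode <= nord))
    stop("invalid `mode`")
  m <- as.matrix(m)
  if (ncol(m) != d[mode])
    stop("ncol(m) must equal the mode-", mode, " dimension")
  perm <- c(mode, setdiff(seq_len(nord), mode))
  tm <- matrix(aperm(unclass(t), perm), nrow = d[mode])
  res <- m %*% tm
  newd <- d; newd[mode] <- nrow(m)
  a <- array(res, dim = newd[perm])
  aperm(a, order(perm))
}

#' Leading eigenvector of a symmetric PSD matrix
#'
#' Unit-norm eigenvector of the largest eigenvalue, with the sign fixed so
#' that the largest-magnitude entry is positive.
#'
#' @param m square symmetric numeric matrix.
#' @return numeric unit vector.
#' @export
leading_eigenvector <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("`m` must be square")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v <- v / sqrt(sum(v^2))
  fix_sign(v)
}

# Flip a vector so that its largest-magnitude entry is positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

# Kronecker vector of the two fixed projectors matching unfold(., mode):
# complementary modes in decreasing order (later mode first, so the earlier
# mode varies fastest).
fixed_kron <- function(w1, w2, w3, mode) {
  switch(mode,
         kron_chain(list(w3, w2)),
         kron_chain(list(w3, w1)),
         kron_chain(list(w2, w1)))
}
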