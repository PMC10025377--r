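#' Decoding metrics and the pseudo-online comparison protocol
#'
#' Performance is summarized by the per-sample cosine similarity between
#' predicted and optimal direction vectors (median and quartiles), and model
#' compactness by the sparsity index: the percentage of mode slices of the
#' coefficient tensor that are entirely zero. Algorithms are compared in a
#' pseudo-online manner: training blocks are replayed in order through the
#' exact online update cadence, the model is frozen, and held-out blocks are
#' scored sample by sample.
#'
#' @name evaluation
NULL

#' Per-sample cosine similarity
#'
#' `CosSim_t = y_t . yhat_t / (||y_t|| ||yhat_t||)`. Samples where either
#' vector has zero norm are masked out (and counted) rather than scored.
#'
#' @param Y,Yhat matrices with one sample per row and matching shapes.
#' @return list with `values` (NA at masked samples), `mask` (TRUE =
#'   usable), `n_used`, `n_skipped`.
#' @export
cosine_similarity_series <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat must have the same shape")
  ny <- sqrt(rowSums(Y^2)); nh <- sqrt(rowSums(Yhat^2))
  mask <- ny > 0 & nh > 0
  vals <- rep(NA_real_, nrow(Y))
  vals[mask] <- rowSums(Y[mask, , drop = FALSE] * Yhat[mask, , drop = FALSE]) /
    (ny[mask] * nh[mask])
  vals <- pmin(1, pmax(-1, vals))
  list(values = vals, mask = mask,
       n_used = sum(mask), n_skipped = sum(!mask))
}

#' Median / quartile summary of a masked series
#'
#' Linear-interpolation quantiles (type 7) of the unmasked values.
#'
#' @param values numeric vector.
#' @param mask logical vector (TRUE = use); defaults to the non-NA entries.
#' @return list of class `cossim_summary`: `median`, `q1`, `q3`, `n_used`,
#'   `n_skipped`.
#' @export
summarize_distribution <- function(values, mask = !is.na(values)) {
  v <- values[mask & !is.na(values)]
  if (length(v) == 0L) stop("no unmasked values to summarize")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 n_used = length(v), n_skipped = sum(!mask)),
            class = "cossim_summary")
}

#' @export
format.cossim_summary <- function(x, digits = 3, ...) {
  sprintf("%.*f (%.*f-%.*f)", digits, x$median, digits, x$q1, digits, x$q3)
}

#' @export
print.cossim_summary <- function(x, ...) {
  cat("CosSim =", format(x), " [n =", x$n_used,
      ", skipped =", x$n_skipped, "]\n")
  invisible(x)
}

#' Sparsity index of a coefficient tensor
#'
#' Percentage of slices along one mode that are entirely zero (every
#' coefficient across all other modes and all outputs exactly 0).
#'
#' @param beta order-4 coefficient array (I1 x I2 x I3 x J).
#' @param mode tensor mode (1, 2 or 3) defining the slices.
#' @return list of class `sparsity_report`: `mode`, `percent_zero_slices`,
#'   `zero_slice_indices`.
#' @export
sparsity_index <- function(beta, mode) {
  d <- dim(beta)
  if (is.null(d) || length(d) != 4L) stop("`beta` must be an order-4 array")
  if (!(mode %in% 1:3)) stop("`mode` must be 1, 2 or 3")
  slice_max <- apply(abs(beta), mode, max)
  zero <- which(slice_max == 0)
  structure(list(mode = as.integer(mode),
                 percent_zero_slices = 100 * length(zero) / d[mode],
                 zero_slice_indices = zero),
            class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("Sparsity (mode %d) = %.2f%% (%d zero slices)\n",
              x$mode, x$percent_zero_slices, length(x$zero_slice_indices)))
  invisible(x)
}

#' Pseudo-online experiment: ordered training, frozen test
#'
#' Feeds the training blocks through [fit_update()] strictly in order (no
#' shuffling, no lookahead), freezes the resulting model, predicts the test
#' blocks sample by sample with the selected `f_star`, and summarizes the
#' cosine similarity and channel sparsity. The training stream is fully
#' consumed before the first test sample is read.
#'
#' @param train_blocks,test_blocks lists of [observation_block()] in time
#'   order.
#' @param pc [penalty_config()].
#' @param dims,J,F,mu1,normalize decoder configuration, see
#'   [rewnpls_init()].
#' @param sparsity_mode tensor mode for the sparsity report (default 3,
#'   channels).
#' @return list of class `pseudo_online_result`: `cossim`
#'   ([summarize_distribution()] output), `sparsity`, `model`, `f_star`,
#'   `f_star_trajectory`, `cos_values` (per-sample series).
#' @export
pseudo_online_experiment <- function(train_blocks, test_blocks, pc,
                                     dims, J = 3L, F = 10L, mu1 = 1,
                                     normalize = TRUE, sparsity_mode = 3L) {
  model <- rewnpls_init(dims = dims, J = J, F = F, mu1 = mu1,
                        normalize = normalize)
  for (b in train_blocks) model <- fit_update(model, b, pc)
  Y <- do.call(rbind, lapply(test_blocks, function(b) b$Y))
  Yhat <- do.call(rbind, lapply(test_blocks, function(b) predict(model, b)))
  cs <- cosine_similarity_series(Y, Yhat)
  summ <- if (cs$n_used > 0) summarize_distribution(cs$values, cs$mask)
          else structure(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                              n_used = 0L, n_skipped = cs$n_skipped),
                         class = "cossim_summary")
  structure(list(
    cossim = summ,
    sparsity = sparsity_index(beta_tensor(model), sparsity_mode),
    model = model, f_star = model$f_star,
    f_star_trajectory = vapply(model$log, `[[`, integer(1), "f_star"),
    cos_values = cs
  ), class = "pseudo_online_result")
}

#' Default penalization-parameter grids
#'
#' `lambda` from 0 to 0.5 in 0.02 steps for the L0.5 and L1 penalties, and
#' from 0 to 0.05 in 0.002 steps for L0 (26 values each); `lambda = 0` is
#' the generic unpenalized baseline.
#'
#' @param p penalty exponent (0, 0.5 or 1).
#' @return numeric vector of 26 lambda values.
#' @export
default_lambda_grid <- function(p) {
  if (!(p %in% c(0, 0.5, 1))) stop("`p` must be 0, 0.5 or 1")
  if (p == 0) seq(0, 0.05, by = 0.002) else seq(0, 0.5, by = 0.02)
}

#' Sweep the penalization parameter over a grid
#'
#' One [pseudo_online_experiment()] per lambda on the *same* blocks (shared
#' data, shared configuration); the first row of the default grids
#' (`lambda = 0`) is the generic unpenalized baseline.
#'
#' @param train_blocks,test_blocks lists of [observation_block()].
#' @param p penalty exponent.
#' @param lam_grid lambda values (default [default_lambda_grid()]).
#' @param penalized_modes tensor modes to penalize (default 3, channels).
#' @inheritParams pseudo_online_experiment
#' @param keep_models keep each fitted model in the result (default FALSE).
#' @return list of class `lambda_sweep`: `table` (data.frame with columns
#'   lambda, p, median, q1, q3, sparsity_percent, n_zero_slices, f_star) and
#'   `results` (per-lambda details).
#' @export
lambda_sweep <- function(train_blocks, test_blocks, p,
                         lam_grid = default_lambda_grid(p),
                         penalized_modes = 3L,
                         dims, J = 3L, F = 10L, mu1 = 1, normalize = TRUE,
                         keep_models = FALSE) {
  if (length(lam_grid) == 0L) stop("`lam_grid` must be nonempty")
  results <- vector("list", length(lam_grid))
  rows <- vector("list", length(lam_grid))
  for (i in seq_along(lam_grid)) {
    lam <- rep(0, 3); lam[penalized_modes] <- lam_grid[i]
    pc <- penalty_config(p = p, lam_per_mode = lam,
                         penalized_modes = penalized_modes)
    res <- pseudo_online_experiment(train_blocks, test_blocks, pc,
                                    dims = dims, J = J, F = F, mu1 = mu1,
                                    normalize = normalize)
    rows[[i]] <- data.frame(
      lambda = lam_grid[i], p = p,
      median = res$cossim$median, q1 = res$cossim$q1, q3 = res$cossim$q3,
      sparsity_percent = res$sparsity$percent_zero_slices,
      n_zero_slices = length(res$sparsity$zero_slice_indices),
      f_star = res$f_star)
    if (!keep_models) res$model <- NULL
    results[[i]] <- res
  }
  structure(list(table = do.call(rbind, rows), results = results),
            class = "lambda_sweep")
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided paired signed-rank test between two equal-length performance
#' series, reported at `alpha` and at the Bonferroni-corrected level
#' `alpha / n_comparisons`. The exact null distribution is used for n <= 25
#' pairs (without ties/zeros), the normal approximation with tie correction
#' otherwise. All-zero differences yield a "no difference" decision with
#' p = 1.
#'
#' @param values_a,values_b paired numeric vectors.
#' @param alpha uncorrected significance level (default 0.05).
#' @param n_comparisons number of comparisons for the Bonferroni correction
#'   (default 1).
#' @return list of class `signed_rank_decision`: `p_value`, `alpha`,
#'   `alpha_bonferroni`, `significant`, `significant_bonferroni`,
#'   `n`, `no_difference`.
#' @export
paired_signed_rank_compare <- function(values_a, values_b, alpha = 0.05,
                                       n_comparisons = 1L) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- b - a
  ab <- alpha / n_comparisons
  if (all(d == 0)) {
    return(structure(list(p_value = 1, alpha = alpha, alpha_bonferroni = ab,
                          significant = FALSE, significant_bonferroni = FALSE,
                          n = length(d), no_difference = TRUE),
                     class = "signed_rank_decision"))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  p <- suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE, exact = exact)$p.value)
  structure(list(p_value = p, alpha = alpha, alpha_bonferroni = ab,
                 significant = p < alpha, significant_bonferroni = p < ab,
                 n = length(d), no_difference = FALSE),
            class = "signed_rank_decision")
}
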