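#' Hyperparameter grid
#'
#' The canonical search grid: number of features k from 10 to 95 in steps of
#' 5 (18 values), 100 lambda values logarithmically spaced between 1e-5 and
#' 1e5, and alpha in {0.001, 0.25, 0.5, 0.75, 1} (0.001 approximates ridge,
#' 1 is the LASSO; alpha = 0 is excluded). k values exceeding the sample
#' size are filtered at use time.
#'
#' @param k_values integer vector (ascending).
#' @param lambda_values positive numeric vector (ascending).
#' @param alpha_values numeric vector in (0, 1] (ascending).
#' @return Object of class `hyper_grid`.
#' @export
hyper_grid <- function(k_values = default_k_grid(),
                       lambda_values = 10^seq(-5, 5, length.out = 100),
                       alpha_values = c(0.001, 0.25, 0.5, 0.75, 1)) {
  k_values <- sort(unique(as.integer(k_values)))
  lambda_values <- sort(unique(as.numeric(lambda_values)))
  alpha_values <- sort(unique(as.numeric(alpha_values)))
  if (any(k_values < 1L)) stop("k values must be positive", call. = FALSE)
  if (any(lambda_values <= 0)) stop("lambda values must be positive", call. = FALSE)
  if (any(alpha_values <= 0 | alpha_values > 1))
    stop("alpha values must be in (0, 1]", call. = FALSE)
  structure(list(k_values = k_values, lambda_values = lambda_values,
                 alpha_values = alpha_values), class = "hyper_grid")
}

#' @export
print.hyper_grid <- function(x, ...) {
  cat(sprintf("<hyper_grid> %d k x %d lambda x %d alpha = %d combinations\n",
              length(x$k_values), length(x$lambda_values),
              length(x$alpha_values),
              length(x$k_values) * length(x$lambda_values) * length(x$alpha_values)))
  invisible(x)
}

# Pooled LOO MSE for every admissible (k, lambda, alpha) combination.
# Returns the long table of pooled MSEs plus the per-combination LOO
# prediction matrices (one n x L matrix per (k, alpha)).
#' @noRd
loo_mse_surface <- function(features_by_k, y, grid, tol = 1e-8,
                            max_iter = 100000L) {
  n <- length(y)
  ks <- intersect(grid$k_values, as.integer(names(features_by_k)))
  ks <- ks[ks <= n]                      # never select models with k > n
  if (!length(ks)) stop("no admissible k values (all exceed n?)", call. = FALSE)
  lam_desc <- rev(grid$lambda_values)    # warm starts run high -> low penalty
  preds <- list()
  rows <- list()
  for (k in ks) {
    Fk <- as.matrix(features_by_k[[as.character(k)]])
    stopifnot(nrow(Fk) == n, ncol(Fk) == k)
    for (a in grid$alpha_values) {
      pm <- cpp_enet_loo(Fk, y, lam_desc, a, tol, as.integer(max_iter))
      pm <- pm[, rev(seq_along(lam_desc)), drop = FALSE]  # ascending lambda
      preds[[paste(k, a)]] <- pm
      mse <- colMeans((pm - y)^2)
      rows[[paste(k, a)]] <- data.frame(k = k, lambda = grid$lambda_values,
                                        alpha = a, mse = mse)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, predictions = preds, k_values = ks)
}

# Tie-break: lowest MSE, then smallest k, then largest lambda, then largest
# alpha (maximum parsimony).
#' @noRd
best_combo <- function(tab) {
  ord <- order(tab$mse, tab$k, -tab$lambda, -tab$alpha)
  tab[ord[1L], c("k", "lambda", "alpha", "mse")]
}

#' @noRd
new_cv_result <- function(...) structure(list(...), class = "cv_result")

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> scheme = %s%s | k = %d, lambda = %.4g, alpha = %.3g | R2 = %.3f, MSE = %.3f, NZ = %d\n",
              x$scheme,
              if (x$aggregation != "none") paste0(" (", x$aggregation, ")") else "",
              x$best$k, x$best$lambda, x$best$alpha,
              x$pooled$r2, x$pooled$mse, x$pooled$nonzero_count))
  invisible(x)
}

#' Leave-one-out hyperparameter selection
#'
#' Grid search over (k, lambda, alpha): for every combination with k <= n,
#' each subject is predicted by a model trained on the remaining n - 1
#' (features standardized within each training fold), and the combination
#' with the lowest pooled LOO MSE wins (ties broken toward smallest k, then
#' largest lambda, then largest alpha). The final model is refitted on all
#' subjects at the winning combination; R-squared, MSE and BIC are reported
#' on the pooled LOO predictions.
#'
#' @param features_by_k named list (names = k as character) of n x k latent
#'   feature matrices, rows aligned to `y`.
#' @param y behavioural scores, length n >= 3.
#' @param grid a [hyper_grid()].
#' @param tol,max_iter coordinate-descent controls.
#' @return A `cv_result` with elements `scheme`, `best`, `model` (final
#'   `enet_model`), `pooled` (predictions, mse, r2, bic, nonzero_count),
#'   `per_fold`, `mse_table`.
#' @export
loo_select <- function(features_by_k, y, grid = hyper_grid(), tol = 1e-8,
                       max_iter = 100000L) {
  y <- as.numeric(y)
  if (length(y) < 3L) stop("need at least 3 scored subjects", call. = FALSE)
  surf <- loo_mse_surface(features_by_k, y, grid, tol, max_iter)
  best <- best_combo(surf$table)
  pm <- surf$predictions[[paste(best$k, best$alpha)]]
  il <- match(best$lambda, grid$lambda_values)
  pred <- pm[, il]
  Fk <- as.matrix(features_by_k[[as.character(best$k)]])
  final <- fit_enet(Fk, y, best$lambda, best$alpha, tol = tol,
                    max_iter = max_iter)
  perf <- r_squared(y, pred)
  new_cv_result(
    scheme = "loo", aggregation = "none",
    best = list(k = best$k, lambda = best$lambda, alpha = best$alpha),
    model = final,
    pooled = list(predictions = pred, mse = perf$mse, r2 = perf$r2,
                  bic = bic_score(y, pred, final$nonzero_count),
                  nonzero_count = final$nonzero_count,
                  residuals = y - pred),
    per_fold = data.frame(fold = seq_along(y), prediction = pred,
                          observed = y),
    mse_table = surf$table)
}

#' Nested leave-one-out hyperparameter selection
#'
#' Outer loop over n folds; within each outer training set of n - 1
#' subjects an inner LOO grid search selects (k, lambda, alpha), and the
#' outer subject is predicted with a model trained on the n - 1 at the
#' inner-selected combination, so tuning never sees the test subject. The
#' final hyperparameters aggregate the n fold-wise selections by the chosen
#' central-tendency rule (mean, median or mode), snapped to the grid. Two
#' performance surfaces are reported: (a) the conservative pooled
#' outer-fold predictions (`pooled`), and (b) a full-sample LOO evaluated at
#' the aggregated combination (`aggregated`), which is how a single final
#' model would be assessed.
#'
#' @inheritParams loo_select
#' @param aggregation `"mean"`, `"median"` or `"mode"`.
#' @return A `cv_result`; `per_fold` records each fold's selected
#'   combination, `best` the aggregated one.
#' @export
nested_loo_select <- function(features_by_k, y, grid = hyper_grid(),
                              aggregation = c("median", "mean", "mode"),
                              tol = 1e-8, max_iter = 100000L) {
  aggregation <- match.arg(aggregation)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("nested LOO needs at least 4 scored subjects", call. = FALSE)
  sel <- vector("list", n)
  outer_pred <- numeric(n)
  for (i in seq_len(n)) {
    fb <- lapply(features_by_k, function(Fk) as.matrix(Fk)[-i, , drop = FALSE])
    inner <- loo_mse_surface(fb, y[-i], grid, tol, max_iter)
    b <- best_combo(inner$table)
    sel[[i]] <- b
    Fk <- as.matrix(features_by_k[[as.character(b$k)]])
    m <- fit_enet(Fk[-i, , drop = FALSE], y[-i], b$lambda, b$alpha,
                  tol = tol, max_iter = max_iter)
    outer_pred[i] <- predict(m, Fk[i, , drop = FALSE])
  }
  sel <- do.call(rbind, sel)
  agg <- aggregate_hyperparams(sel, aggregation, grid)
  # surface (b): full-sample LOO at the aggregated combination
  Fk <- as.matrix(features_by_k[[as.character(agg$k)]])
  pm <- cpp_enet_loo(Fk, y, agg$lambda, agg$alpha, tol, as.integer(max_iter))
  agg_pred <- pm[, 1L]
  final <- fit_enet(Fk, y, agg$lambda, agg$alpha, tol = tol,
                    max_iter = max_iter)
  outer_perf <- r_squared(y, outer_pred)
  agg_perf <- r_squared(y, agg_pred)
  new_cv_result(
    scheme = "nested_loo", aggregation = aggregation,
    best = agg, model = final,
    pooled = list(predictions = outer_pred, mse = outer_perf$mse,
                  r2 = outer_perf$r2,
                  bic = bic_score(y, outer_pred, final$nonzero_count),
                  nonzero_count = final$nonzero_count,
                  residuals = y - outer_pred),
    aggregated = list(predictions = agg_pred, mse = agg_perf$mse,
                      r2 = agg_perf$r2,
                      bic = bic_score(y, agg_pred, final$nonzero_count)),
    per_fold = data.frame(fold = seq_len(n), observed = y,
                          prediction = outer_pred, k = sel$k,
                          lambda = sel$lambda, alpha = sel$alpha))
}

#' Aggregate per-fold hyperparameter selections
#'
#' Central-tendency summary of the fold-wise (k, lambda, alpha) selections
#' of a nested cross-validation. The mean of lambda is taken on the log10
#' scale (lambda is a scale parameter); k and alpha are averaged naturally.
#' Every aggregate is snapped to the nearest admissible grid value (lambda
#' in log10 distance); for the mode, ties go to the smallest value
#' (parsimony), as do exact snapping ties.
#'
#' @param selections data frame with columns `k`, `lambda`, `alpha` (one row
#'   per fold).
#' @param rule `"mean"`, `"median"` or `"mode"`.
#' @param grid a [hyper_grid()] to snap to.
#' @return List with `k`, `lambda`, `alpha`.
#' @export
aggregate_hyperparams <- function(selections, rule = c("mean", "median", "mode"),
                                  grid = hyper_grid()) {
  rule <- match.arg(rule)
  stopifnot(nrow(selections) >= 1L)
  center <- switch(rule,
    mean = list(k = mean(selections$k),
                lambda = 10^mean(log10(selections$lambda)),
                alpha = mean(selections$alpha)),
    median = list(k = stats::median(selections$k),
                  lambda = stats::median(selections$lambda),
                  alpha = stats::median(selections$alpha)),
    mode = list(k = mode_smallest(selections$k),
                lambda = mode_smallest(selections$lambda),
                alpha = mode_smallest(selections$alpha)))
  list(k = snap_to_grid(center$k, grid$k_values),
       lambda = snap_to_grid(center$lambda, grid$lambda_values, log = TRUE),
       alpha = snap_to_grid(center$alpha, grid$alpha_values))
}

# Most frequent value; ties resolved toward the smallest value.
#' @noRd
mode_smallest <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])  # table is sorted ascending by value
}

# Nearest grid value (optionally in log10 distance); equidistant -> smaller.
#' @noRd
snap_to_grid <- function(x, values, log = FALSE) {
  d <- if (log) abs(log10(values) - log10(x)) else abs(values - x)
  values[which.min(d)]  # which.min takes the first (smallest) on ties
}

#' Pairwise comparison of model residuals
#'
#' Two-sided Wilcoxon signed-rank tests on the paired squared residuals of
#' every unordered pair of models, Bonferroni-corrected: with m pairs a
#' difference is flagged significant when p < alpha_level / m.
#'
#' @param residuals_by_method named list of either `cv_result` objects or
#'   numeric residual vectors (residuals are squared internally; all equal
#'   length).
#' @param alpha_level family-wise error target (default 0.05).
#' @return Data frame with one row per pair: `method_a`, `method_b`,
#'   `statistic`, `p_value`, `n_used`, `threshold`, `significant`.
#' @export
compare_models <- function(residuals_by_method, alpha_level = 0.05) {
  sq <- lapply(residuals_by_method, function(x) {
    if (inherits(x, "cv_result")) x$pooled$residuals^2 else as.numeric(x)^2
  })
  if (length(sq) < 2L) stop("need at least two models to compare", call. = FALSE)
  if (length(unique(lengths(sq))) != 1L)
    stop("residual vectors must have equal length (paired)", call. = FALSE)
  nm <- names(sq) %||% paste0("model_", seq_along(sq))
  pairs <- utils::combn(seq_along(sq), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    w <- wilcoxon_signed_rank(sq[[a]], sq[[b]])
    data.frame(method_a = nm[a], method_b = nm[b], statistic = w$statistic,
               p_value = w$p_value, n_used = w$n_used,
               threshold = alpha_level / m,
               significant = w$p_value < alpha_level / m)
  })
  do.call(rbind, rows)
}
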