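# Shared contract for the four unsupervised extraction methods.
#
# A feature_model holds a synthesis basis (p x k, X ~ F basis' + center),
# an optional analysis forward_map (p x k, F = (X - center) forward_map;
# present for PCA/ICA, absent for DL/NNMF whose encodings are solutions of
# per-row optimization problems), the training features F_train and fit
# metadata. All methods are exercised through transform_features() and
# reconstruction_error() so they can be compared on equal terms.

#' @noRd
new_feature_model <- function(method, k, basis, forward_map, center, F_train,
                              fit_info, ...) {
  structure(list(method = method, k = as.integer(k), basis = basis,
                 forward_map = forward_map, center = center,
                 F_train = F_train, fit_info = fit_info, ...),
            class = "feature_model")
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("<feature_model> method = %s, k = %d, p = %d%s\n", x$method,
              x$k, nrow(x$basis),
              if (isTRUE(x$fit_info$converged)) "" else " (not converged)"))
  invisible(x)
}

#' @noRd
as_cohort_matrix <- function(X) {
  if (inherits(X, "cohort_table")) X$X else as.matrix(X)
}

#' Fit an unsupervised feature-extraction model
#'
#' Front-end dispatching to [fit_pca()], [fit_ica()], [fit_dl()] or
#' [fit_nnmf()].
#'
#' @param X a [cohort_table()] or n x p numeric matrix.
#' @param method one of `"pca"`, `"ica"`, `"dl"`, `"nnmf"`.
#' @param k number of latent features.
#' @param ... passed to the method-specific fitter.
#' @return A `feature_model`.
#' @export
fit_features <- function(X, method = c("pca", "ica", "dl", "nnmf"), k, ...) {
  method <- match.arg(method)
  switch(method,
         pca = fit_pca(X, k, ...),
         ica = fit_ica(X, k, ...),
         dl = fit_dl(X, k, ...),
         nnmf = fit_nnmf(X, k, ...))
}

#' Project new data into a fitted latent space
#'
#' PCA/ICA use the exact linear analysis map F = (X - center) forward_map.
#' DL solves a per-row L1-regularized (lasso) coding problem against the
#' dictionary at the model's sparsity; NNMF solves per-row nonnegative least
#' squares against the basis after applying the model's negativity policy.
#'
#' @param model a fitted `feature_model`.
#' @param X new data with the same number of edge columns.
#' @return n x k matrix of latent features.
#' @export
transform_features <- function(model, X) {
  stopifnot(inherits(model, "feature_model"))
  X <- as_cohort_matrix(X)
  p <- nrow(model$basis)
  if (ncol(X) != p)
    stop(sprintf("data has %d columns, model expects %d", ncol(X), p), call. = FALSE)
  switch(model$method,
    pca = ,
    ica = sweep(X, 2L, model$center) %*% model$forward_map,
    dl = {
      W <- model$basis
      G <- crossprod(W)
      Ct <- X %*% W
      rowwise_solve(nrow(X), model$k, function(i)
        cpp_lasso_gram(G, Ct[i, ], model$dl_sparsity, numeric(model$k),
                       1e-8, 1000L))
    },
    nnmf = {
      Xp <- apply_negativity_policy(X, model$negativity_policy, model$shift)
      B <- model$basis
      G <- crossprod(B)
      Ct <- Xp %*% B
      rowwise_solve(nrow(Xp), model$k, function(i)
        cpp_nnls_gram(G, Ct[i, ], numeric(model$k), 1e-10, 1000L))
    })
}

#' @noRd
rowwise_solve <- function(n, k, solve_row) {
  res <- vapply(seq_len(n), function(i) as.numeric(solve_row(i)), numeric(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' @param object,newdata,... S3 predict interface to [transform_features()].
#' @rdname transform_features
#' @export
predict.feature_model <- function(object, newdata, ...) {
  transform_features(object, newdata)
}

#' Reconstruction mean squared error
#'
#' Projects `X` into the latent space and back, and returns the elementwise
#' mean squared error between the data and its rank-k reconstruction,
#' MSE = ||X - (F basis' + center)||_F^2 / (n p). For centered methods the
#' center is added back so all methods are compared on the same scale; for
#' NNMF the comparison is on the policy-transformed (e.g. shifted)
#' nonnegative data, which preserves all variance structure.
#'
#' @param model a fitted `feature_model`.
#' @param X data matrix or [cohort_table()]; defaults to reconstructing the
#'   training data.
#' @return Scalar MSE.
#' @export
reconstruction_error <- function(model, X) {
  X <- as_cohort_matrix(X)
  F_new <- transform_features(model, X)
  target <- if (model$method == "nnmf")
    apply_negativity_policy(X, model$negativity_policy, model$shift)
  else X
  R <- F_new %*% t(model$basis)
  if (any(model$center != 0)) R <- sweep(R, 2L, model$center, `+`)
  mean((target - R)^2)
}

#' Default number-of-features grid
#'
#' The canonical grid for the number of extracted features: 10 to 95 in
#' steps of 5, eighteen values.
#' @return Integer vector.
#' @export
default_k_grid <- function() seq(10L, 95L, by = 5L)

#' Reconstruction-error curve across methods and k
#'
#' Computes the reconstruction MSE for every (method, k) combination. PCA is
#' deterministic and nested in k, so it is fitted once at the largest k and
#' truncated; the other methods are refitted at every k with seeds derived
#' from `seed`. Grid values exceeding n - 1 are dropped with a warning.
#'
#' @param X [cohort_table()] or matrix.
#' @param methods subset of `c("pca", "ica", "dl", "nnmf")`.
#' @param k_grid integer grid of k values (default [default_k_grid()]).
#' @param seed base seed for the stochastic methods.
#' @param ... extra arguments passed to every fitter.
#' @return Data frame with columns `method`, `k`, `mse`.
#' @export
error_curve <- function(X, methods = c("pca", "ica", "dl", "nnmf"),
                        k_grid = default_k_grid(), seed = 1L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  Xm <- as_cohort_matrix(X)
  n <- nrow(Xm)
  ok <- k_grid <= n - 1L
  if (!all(ok)) {
    warning(sprintf("dropping %d k value(s) above n - 1 = %d", sum(!ok), n - 1L))
    k_grid <- k_grid[ok]
  }
  if (!length(k_grid)) stop("empty k grid after filtering", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  out <- list()
  for (m in methods) {
    if (m == "pca") {
      full <- fit_pca(Xm, max(k_grid))
      mses <- vapply(k_grid, function(k)
        reconstruction_error(truncate_features(full, k), Xm), numeric(1))
    } else {
      mses <- vapply(seq_along(k_grid), function(ik) {
        fm <- fit_features(Xm, m, k_grid[ik],
                           seed = seed + 1000L * match(m, methods) + ik, ...)
        reconstruction_error(fm, Xm)
      }, numeric(1))
    }
    out[[m]] <- data.frame(method = m, k = k_grid, mse = mses)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Truncate a PCA model to fewer components
#'
#' Valid only for PCA, whose components are nested: the leading k columns of
#' a larger fit are exactly the k-component fit.
#'
#' @param model a PCA `feature_model`.
#' @param k target number of components (<= model$k).
#' @return A `feature_model` with k components.
#' @export
truncate_features <- function(model, k) {
  stopifnot(inherits(model, "feature_model"))
  if (model$method != "pca")
    stop("only PCA models are nested in k and can be truncated", call. = FALSE)
  if (k > model$k) stop("k exceeds the fitted number of components", call. = FALSE)
  idx <- seq_len(k)
  new_feature_model("pca", k, model$basis[, idx, drop = FALSE],
                    model$forward_map[, idx, drop = FALSE], model$center,
                    model$F_train[, idx, drop = FALSE], model$fit_info)
}

#' Serialize a feature model to a directory
#'
#' Writes the basis, forward map (if any), center and training features as
#' delimited tables plus a JSON file with the fit metadata.
#'
#' @param model a `feature_model`. @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_feature_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE,
                                   col.names = FALSE)
  wt(model$basis, "basis.tsv")
  if (!is.null(model$forward_map)) wt(model$forward_map, "forward_map.tsv")
  wt(model$center, "center.tsv")
  wt(model$F_train, "F_train.tsv")
  meta <- c(list(method = model$method, k = model$k), model$fit_info,
            if (!is.null(model$dl_sparsity)) list(dl_sparsity = model$dl_sparsity),
            if (!is.null(model$negativity_policy))
              list(negativity_policy = model$negativity_policy,
                   shift = model$shift))
  meta$objective_path <- NULL
  jsonlite::write_json(meta, file.path(dir, "fit_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
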