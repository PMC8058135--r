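#' Principal component analysis
#'
#' Centers the data and takes the top-k right singular vectors as the basis,
#' in descending singular-value order. With p > n only n - 1 non-trivial
#' components exist, so k is capped at n - 1. PCA is deterministic up to
#' component sign; signs are fixed so each component's largest-magnitude
#' loading is positive. The basis is orthonormal and doubles as the analysis
#' forward map, so F = (X - center) basis.
#'
#' @param X [cohort_table()] or n x p matrix.
#' @param k number of components, 1 <= k <= n - 1.
#' @return A `feature_model` (fit_info carries the full singular-value
#'   spectrum of the centered data).
#' @export
fit_pca <- function(X, k) {
  X <- as_cohort_matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop(sprintf("k must be in 1..n-1 = %d (rank limit for centered data)", n - 1L),
         call. = FALSE)
  if (k > ncol(X)) stop("k exceeds the number of edges", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = 0L, nv = k)
  V <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(k), function(j) {
    v <- V[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  V <- sweep(V, 2L, flip, `*`)
  new_feature_model("pca", k, basis = V, forward_map = V, center = center,
                    F_train = Xc %*% V,
                    fit_info = list(seed = NA_integer_, iterations = 1L,
                                    converged = TRUE,
                                    objective = sum(sv$d[-seq_len(k)]^2),
                                    singular_values = sv$d))
}

#' Independent component analysis (fixed-point, log-cosh)
#'
#' Centers the data, whitens it with PCA to k dimensions, and runs the
#' symmetric fixed-point algorithm with the log-cosh contrast to find an
#' orthogonal rotation of the whitened coordinates with maximally
#' non-Gaussian, independent sources. Sources have unit sample variance.
#' Because whitening is PCA-based, the basis spans exactly the top-k PCA
#' subspace and the reconstruction F basis' + center equals the rank-k PCA
#' reconstruction, so ICA and PCA share the same reconstruction MSE at
#' matched k.
#'
#' @inheritParams fit_pca
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed seed for the random initial rotation.
#' @return A `feature_model`; non-convergence yields a warning and
#'   `fit_info$converged = FALSE`, not an error.
#' @export
fit_ica <- function(X, k, max_iter = 1000L, tol = 1e-4, seed = 1L) {
  X <- as_cohort_matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L)
    stop(sprintf("k must be in 1..n-1 = %d", n - 1L), call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-12 * sv$d[1]))
    stop("data rank below k; cannot whiten", call. = FALSE)
  Z <- sqrt(n - 1) * sv$u                     # n x k, unit-variance whitened
  set.seed(seed)
  R <- matrix(rnorm(k * k), k, k)
  R <- sym_decorrelate(R)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- Z %*% R
    G <- tanh(S)
    Rnew <- crossprod(Z, G) / n - R %*% diag(colMeans(1 - G^2), k, k)
    Rnew <- sym_decorrelate(Rnew)
    delta <- max(abs(abs(colSums(Rnew * R)) - 1))
    R <- Rnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations (delta = %.2e)",
                    max_iter, delta))
  scale <- sqrt(n - 1)
  forward <- sv$v %*% diag(scale / d, k, k) %*% R       # analysis map
  basis <- sv$v %*% diag(d / scale, k, k) %*% R         # synthesis map
  new_feature_model("ica", k, basis = basis, forward_map = forward,
                    center = center, F_train = Z %*% R,
                    fit_info = list(seed = seed, iterations = it,
                                    converged = converged,
                                    objective = NA_real_,
                                    singular_values = sv$d))
}

# Symmetric decorrelation R (R'R)^{-1/2} via eigendecomposition.
#' @noRd
sym_decorrelate <- function(R) {
  e <- eigen(crossprod(R), symmetric = TRUE)
  R %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                           length(e$values)) %*% t(e$vectors)
}
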