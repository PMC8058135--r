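#' Dictionary learning (sparse coding)
#'
#' Alternating minimization of 0.5 ||X - F W'||_F^2 + lambda ||F||_1 subject
#' to unit-norm dictionary columns ||W_j||_2 <= 1. The code step solves a
#' lasso problem per subject row by coordinate descent; the dictionary step
#' is block coordinate descent over columns with projection onto the norm
#' ball, so the objective is non-increasing at every iteration (monitored;
#' a violation or NaN raises an error). The data are not centered.
#'
#' @param X [cohort_table()] or n x p matrix.
#' @param k number of dictionary atoms.
#' @param dl_sparsity L1 penalty on the codes (lambda > 0); default 1.
#' @param max_iter,tol outer alternation controls (relative objective
#'   decrease).
#' @param seed seed for dictionary initialization.
#' @return A `feature_model` (basis = dictionary; no forward map;
#'   `fit_info$objective_path` records the monitored objective).
#' @export
fit_dl <- function(X, k, dl_sparsity = 1, max_iter = 60L, tol = 1e-6, seed = 1L) {
  X <- as_cohort_matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (dl_sparsity <= 0) stop("dl_sparsity must be > 0", call. = FALSE)
  set.seed(seed)
  # init: leading right singular vectors (unit norm), randomized completion
  k0 <- min(k, n, p)
  sv <- svd(X, nu = 0L, nv = k0)
  W <- matrix(rnorm(p * k, sd = 1 / sqrt(p)), p, k)
  W[, seq_len(k0)] <- sv$v
  W <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), 1e-12), `/`)
  Fm <- matrix(0, n, k)
  obj_path <- numeric(0)
  obj_old <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # sparse coding step
    G <- crossprod(W)
    Ct <- X %*% W
    for (i in seq_len(n))
      Fm[i, ] <- cpp_lasso_gram(G, Ct[i, ], dl_sparsity, Fm[i, ], 1e-8, 1000L)
    # dictionary step: column-wise exact updates under the norm constraint
    A <- crossprod(Fm)            # k x k
    B <- crossprod(X, Fm)         # p x k
    for (j in seq_len(k)) {
      if (A[j, j] > 1e-12) {
        u <- W[, j] + (B[, j] - W %*% A[, j]) / A[j, j]
        W[, j] <- u / max(1, sqrt(sum(u^2)))
      }
    }
    obj <- 0.5 * sum((X - Fm %*% t(W))^2) + dl_sparsity * sum(abs(Fm))
    if (!is.finite(obj)) stop("dictionary learning objective diverged", call. = FALSE)
    obj_path <- c(obj_path, obj)
    if (obj_old - obj < tol * max(obj_old, 1)) { converged <- TRUE; break }
    obj_old <- obj
  }
  new_feature_model("dl", k, basis = W, forward_map = NULL,
                    center = rep(0, p), F_train = Fm,
                    fit_info = list(seed = seed, iterations = it,
                                    converged = converged, objective = obj,
                                    objective_path = obj_path),
                    dl_sparsity = dl_sparsity)
}

#' @noRd
apply_negativity_policy <- function(X, policy, shift = 0) {
  switch(policy,
         shift = X + shift,
         clip = pmax(X, 0),
         reject = {
           if (any(X < 0))
             stop("negative entries with negativity_policy = 'reject'", call. = FALSE)
           X
         })
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Factorizes X ~ W H (W: n x k codes, H: k x p basis rows) by the
#' multiplicative-update algorithm for the Frobenius loss, which keeps both
#' factors nonnegative and decreases the objective monotonically. Several
#' seeded random restarts are run and the best objective kept. Connectivity
#' values can be negative, so a negativity policy is applied first:
#' `"shift"` (default) subtracts the global minimum, `"clip"` zeroes
#' negatives, `"reject"` errors. Reconstruction error is computed on the
#' policy-transformed data.
#'
#' @param X [cohort_table()] or n x p matrix.
#' @param k rank of the factorization.
#' @param negativity_policy one of `"shift"`, `"clip"`, `"reject"`.
#' @param max_iter,tol update-loop controls (relative objective decrease).
#' @param n_restarts seeded random restarts; best kept.
#' @param seed base seed.
#' @return A `feature_model` with `F_train = W`, `basis = t(H)`, no forward
#'   map, and the applied policy/shift recorded.
#' @export
fit_nnmf <- function(X, k, negativity_policy = c("shift", "clip", "reject"),
                     max_iter = 200L, tol = 1e-6, n_restarts = 3L, seed = 1L) {
  X <- as_cohort_matrix(X)
  negativity_policy <- match.arg(negativity_policy)
  shift <- if (negativity_policy == "shift") max(0, -min(X)) else 0
  Xp <- apply_negativity_policy(X, negativity_policy, shift)
  n <- nrow(Xp); p <- ncol(Xp)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    scale0 <- sqrt(max(mean(Xp), eps) / k)
    W <- matrix(runif(n * k, min = eps), n, k) * scale0
    H <- matrix(runif(k * p, min = eps), k, p) * scale0
    obj_path <- numeric(0)
    obj_old <- Inf
    it <- 0L
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      H <- H * (crossprod(W, Xp)) / (crossprod(W) %*% H + eps)
      W <- W * (Xp %*% t(H)) / (W %*% tcrossprod(H) + eps)
      obj <- sum((Xp - W %*% H)^2)
      obj_path <- c(obj_path, obj)
      if (obj_old - obj < tol * max(obj_old, eps)) { converged <- TRUE; break }
      obj_old <- obj
    }
    if (is.null(best) || obj < best$obj)
      best <- list(W = W, H = H, obj = obj, obj_path = obj_path,
                   iterations = it, converged = converged, seed = seed + r - 1L)
  }
  new_feature_model("nnmf", k, basis = t(best$H), forward_map = NULL,
                    center = rep(0, p), F_train = best$W,
                    fit_info = list(seed = best$seed, iterations = best$iterations,
                                    converged = best$converged,
                                    objective = best$obj,
                                    objective_path = best$obj_path,
                                    n_restarts = n_restarts),
                    negativity_policy = negativity_policy, shift = shift)
}
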