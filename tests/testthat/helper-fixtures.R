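# Small in-code fixtures shared across test files.

# random symmetric matrix with zero diagonal
sym_matrix <- function(P, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(P * P), P)
  m <- (a + t(a)) / 2
  diag(m) <- 0
  m
}

toy_atlas <- function(P = 10, M = 3) {
  parcel_atlas(sprintf("p%02d", seq_len(P)),
               rep(LETTERS[seq_len(M)], length.out = P))
}

# small random cohort matrix (no structure)
rand_cohort <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# exact low-rank instance: X = F W' (+ optional noise), returns parts
lowrank_instance <- function(n = 30, p = 60, k = 4, noise = 0, seed = 1) {
  set.seed(seed)
  F <- matrix(rnorm(n * k), n, k)
  W <- matrix(rnorm(p * k), p, k)
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  X <- F %*% t(W)
  if (noise > 0) X <- X + noise * matrix(rnorm(n * p), n, p)
  list(X = X, F = F, W = W)
}

# features-by-k list for selection tests, from a PCA fit
pca_features_by_k <- function(X, k_values) {
  ms <- extract_feature_sets(X, "pca", k_values)
  lapply(ms, function(m) m$F_train)
}

# direct (1/2n)RSS + penalty evaluation of the elastic-net objective
enet_objective_direct <- function(Z, y, b0, beta, lambda, alpha) {
  n <- length(y)
  sum((y - b0 - as.numeric(Z %*% beta))^2) / (2 * n) +
    lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

# KKT residual of the elastic-net solution (max violation over coordinates)
enet_kkt_violation <- function(Z, y, b0, beta, lambda, alpha) {
  n <- length(y)
  r <- y - b0 - as.numeric(Z %*% beta)
  g <- as.numeric(crossprod(Z, r)) / n - lambda * (1 - alpha) * beta
  viol <- numeric(length(beta))
  nz <- beta != 0
  viol[nz] <- abs(g[nz] - lambda * alpha * sign(beta[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - lambda * alpha)
  max(c(viol, abs(mean(r))))  # intercept optimality: residuals mean zero
}
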