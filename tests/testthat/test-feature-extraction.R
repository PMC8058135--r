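test_that("PCA reconstruction error matches the discarded-eigenvalue closed form", {
  X <- rand_cohort(20, 50, seed = 2)
  d2 <- svd(scale(X, scale = FALSE), nu = 0, nv = 0)$d^2  # full oracle
  for (k in c(1, 5, 10, 19)) {
    fm <- fit_pca(X, k)
    expect_equal(reconstruction_error(fm, X),
                 sum(d2[-seq_len(k)]) / (20 * 50), tolerance = 1e-10)
  }
  # monotone in k; zero at full retained rank
  errs <- vapply(1:19, function(k) reconstruction_error(fit_pca(X, k), X),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[19], 1e-12)

  # points exactly on a line: one component suffices
  set.seed(1)
  t <- rnorm(30)
  line <- cbind(2 * t + 1, -t + 3)
  expect_lt(reconstruction_error(fit_pca(line, 1), line), 1e-20)
})

test_that("PCA is deterministic, sign-fixed, nested in k, and centers correctly", {
  X <- rand_cohort(15, 40, seed = 7)
  f1 <- fit_pca(X, 8)
  f2 <- fit_pca(X, 8)
  expect_identical(f1$basis, f2$basis)
  expect_equal(crossprod(f1$basis), diag(8), tolerance = 1e-8)
  expect_identical(f1$forward_map, f1$basis)
  # largest-|loading| entry of each component is positive
  for (j in 1:8) expect_gt(f1$basis[which.max(abs(f1$basis[, j])), j], 0)
  # truncation equals a direct smaller fit
  f3 <- fit_pca(X, 3)
  tr <- truncate_features(f1, 3)
  expect_equal(tr$basis, f3$basis, tolerance = 1e-10)
  expect_equal(tr$F_train, f3$F_train, tolerance = 1e-10)
  # transform of the mean row is the zero feature vector
  expect_equal(as.numeric(transform_features(f1, matrix(f1$center, 1))),
               rep(0, 8), tolerance = 1e-10)
  expect_error(fit_pca(X, 15), "n-1")
})

test_that("ICA recovers independent non-Gaussian sources up to sign/permutation", {
  set.seed(10)
  n <- 400; k <- 3; p <- 25
  S <- matrix(runif(n * k, -sqrt(3), sqrt(3)), n, k)
  A <- matrix(rnorm(p * k), p, k)
  X <- S %*% t(A)
  fm <- fit_ica(X, k, seed = 4)
  expect_true(fm$fit_info$converged)
  C <- abs(cor(fm$F_train, S))
  # greedy assignment on |correlation|
  matched <- numeric(k)
  Cw <- C
  for (s in seq_len(k)) {
    ij <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    matched[s] <- Cw[ij[1], ij[2]]
    Cw[ij[1], ] <- -1; Cw[, ij[2]] <- -1
  }
  expect_true(all(matched > 0.95))
})

test_that("ICA shares the PCA subspace: equal reconstruction error, exact transform", {
  X <- rand_cohort(30, 80, seed = 5)
  for (k in c(2, 6, 10)) {
    fi <- suppressWarnings(fit_ica(X, k, seed = 1))
    fp <- fit_pca(X, k)
    expect_equal(reconstruction_error(fi, X), reconstruction_error(fp, X),
                 tolerance = 1e-6)
    expect_equal(transform_features(fi, X), fi$F_train, tolerance = 1e-10)
    # unit-variance sources
    expect_equal(apply(fi$F_train, 2, sd), rep(1, k), tolerance = 1e-8)
  }
})

test_that("dictionary learning honours its penalty, constraints and monotonicity", {
  lr <- lowrank_instance(n = 25, p = 40, k = 3, seed = 6)
  X <- lr$X
  # huge penalty: all codes exactly zero, MSE = mean of squares
  fm_big <- fit_dl(X, 3, dl_sparsity = 1e4, max_iter = 5, seed = 1)
  expect_true(all(fm_big$F_train == 0))
  expect_equal(reconstruction_error(fm_big, X), mean(X^2), tolerance = 1e-12)

  fm <- fit_dl(X, 3, dl_sparsity = 0.01, seed = 1)
  expect_lte(max(sqrt(colSums(fm$basis^2))), 1 + 1e-8)
  path <- fm$fit_info$objective_path
  expect_true(all(diff(path) <= 1e-8 * pmax(path[-length(path)], 1)))
  # small penalty on exact rank-k data: near-perfect reconstruction
  expect_lt(reconstruction_error(fm, X), 0.01 * mean(scale(X, scale = FALSE)^2))

  # per-row transform attains at least training-objective quality
  obj_row <- function(f, x, W, lam) 0.5 * sum((x - W %*% f)^2) + lam * sum(abs(f))
  Fnew <- transform_features(fm, X)
  for (i in c(1, 10, 25)) {
    expect_lte(obj_row(Fnew[i, ], X[i, ], fm$basis, fm$dl_sparsity),
               obj_row(fm$F_train[i, ], X[i, ], fm$basis, fm$dl_sparsity) + 1e-6)
  }
})

test_that("NNMF multiplicative updates keep factors nonnegative and objective monotone", {
  set.seed(3)
  w <- abs(rnorm(20)); h <- abs(rnorm(35))
  X1 <- outer(w, h)
  fm1 <- fit_nnmf(X1, 1, max_iter = 500, tol = 1e-14, seed = 2)
  expect_lt(reconstruction_error(fm1, X1), 1e-8)

  lr <- lowrank_instance(n = 20, p = 30, k = 3, seed = 4)
  fm <- fit_nnmf(lr$X, 3, seed = 1)
  expect_gte(min(fm$F_train), 0)
  expect_gte(min(fm$basis), 0)
  path <- fm$fit_info$objective_path
  expect_true(all(diff(path) <= 1e-8 * pmax(path[-length(path)], 1)))
  expect_identical(fm$negativity_policy, "shift")
  expect_equal(fm$shift, max(0, -min(lr$X)))

  expect_error(fit_nnmf(lr$X, 3, negativity_policy = "reject"), "negative")
  fmc <- fit_nnmf(lr$X, 2, negativity_policy = "clip", max_iter = 20)
  expect_identical(fmc$shift, 0)
})

test_that("reconstruction error is invariant to subject permutation (exact for PCA)", {
  X <- rand_cohort(18, 30, seed = 13)
  perm <- sample(18)
  expect_identical(reconstruction_error(fit_pca(X, 4), X),
                   reconstruction_error(fit_pca(X[perm, ], 4), X[perm, ]))
  e1 <- reconstruction_error(fit_nnmf(X, 3, seed = 2), X)
  e2 <- reconstruction_error(fit_nnmf(X[perm, ], 3, seed = 2), X[perm, ])
  expect_equal(e1, e2, tolerance = 0.05)  # stochastic fit, same law
})

test_that("reconstruction_error equals a brute-force elementwise computation", {
  m <- sym_matrix(10, seed = 12)
  X <- t(vapply(1:10, function(s) as.numeric(vectorize_connectome(sym_matrix(10, s))),
                numeric(45)))
  fm <- fit_pca(X, 4)
  F <- transform_features(fm, X)
  R <- F %*% t(fm$basis)
  R <- sweep(R, 2, fm$center, `+`)
  acc <- 0
  for (i in 1:10) for (j in 1:45) acc <- acc + (X[i, j] - R[i, j])^2
  expect_equal(reconstruction_error(fm, X), acc / (10 * 45), tolerance = 1e-12)
})

test_that("error_curve filters k, nests PCA, and orders methods on shared subspaces", {
  lr <- lowrank_instance(n = 30, p = 45, k = 5, seed = 9)
  # k = 8 would exceed the data rank (noiseless rank-5); stay within it.
  # ICA may also warn about non-convergence on these rotation-degenerate
  # latents, so assert the k-filter warning on a PCA-only call
  expect_warning(error_curve(lr$X, "pca", k_grid = c(2, 40)), "dropping")
  curve <- suppressWarnings(error_curve(lr$X, c("pca", "ica"),
                                        k_grid = c(2, 4, 5, 40), seed = 1))
  expect_setequal(unique(curve$k), c(2, 4, 5))
  wide <- reshape(curve, idvar = "k", timevar = "method", direction = "wide")
  expect_true(all(wide$mse.pca <= wide$mse.ica + 1e-6))
  # noiseless rank-5 data: exact at k = 5 for the subspace methods
  expect_lt(curve$mse[curve$method == "pca" & curve$k == 5], 1e-6)
  expect_lt(curve$mse[curve$method == "ica" & curve$k == 5], 1e-6)
  # dl reaches it too with a small penalty
  dlc <- error_curve(lr$X, "dl", k_grid = 5, dl_sparsity = 1e-4, seed = 1)
  expect_lt(dlc$mse, 1e-4)
})
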