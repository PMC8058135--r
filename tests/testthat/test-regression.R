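test_that("standardization uses training statistics and is idempotent", {
  F_tr <- rand_cohort(12, 5, seed = 1)
  F_ap <- rand_cohort(4, 5, seed = 2)
  s <- standardize_features(F_tr, F_ap)
  expect_equal(colMeans(s$Z_train), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(s$Z_train, 2, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(as.numeric(standardize_features(cbind(1:3))$Z_train),
               (1:3 - 2) / 1, ignore_attr = TRUE)
  # apply row equal to the training mean maps to zero
  s2 <- standardize_features(F_tr, matrix(colMeans(F_tr), 1))
  expect_equal(as.numeric(s2$Z_apply), rep(0, 5), tolerance = 1e-12)
  # idempotent on the already-standardized training set
  s3 <- standardize_features(s$Z_train)
  expect_equal(s3$Z_train, s$Z_train, tolerance = 1e-12, ignore_attr = TRUE)
  # constant column flagged, sd forced to 1
  sc <- standardize_features(cbind(rep(2, 6), rnorm(6)))
  expect_identical(sc$standardizer$constant, c(TRUE, FALSE))
  expect_equal(sc$standardizer$sds[1], 1)
})

test_that("elastic-net solutions satisfy the KKT conditions of the penalized objective", {
  set.seed(20)
  Z <- rand_cohort(40, 12, seed = 20)
  y <- rnorm(40)
  for (alpha in c(0.001, 0.5, 1)) for (lambda in c(0.01, 0.1, 1)) {
    m <- fit_enet(Z, y, lambda, alpha, standardize = FALSE)
    expect_lt(enet_kkt_violation(Z, y, m$intercept, m$beta, lambda, alpha),
              1e-6)
    expect_equal(m$objective,
                 enet_objective_direct(Z, y, m$intercept, m$beta, lambda, alpha),
                 tolerance = 1e-10)
    # objective at the solution beats the null fit
    expect_lte(m$objective,
               enet_objective_direct(Z, y, mean(y), rep(0, 12), lambda, alpha))
  }
})

test_that("LASSO nulls out exactly at the KKT threshold and matches soft-thresholding", {
  set.seed(4)
  n <- 50; k <- 8
  Z <- rand_cohort(n, k, seed = 4)
  Zc <- scale(Z, scale = FALSE)
  y <- rnorm(n)
  lam_max <- max(abs(crossprod(Zc, y - mean(y)))) / n
  m0 <- fit_enet(Z, y, lam_max * 1.0001, 1, standardize = FALSE)
  expect_identical(m0$beta, rep(0, k))
  expect_identical(m0$nonzero_count, 0L)
  expect_equal(m0$intercept, mean(y))

  # orthonormal design in the (1/n) Z'Z = I sense: closed-form soft threshold
  # (QR of centered columns stays centered, so the intercept decouples)
  Zo <- sqrt(n) * qr.Q(qr(scale(rand_cohort(n, k, seed = 5), scale = FALSE)))
  rho <- as.numeric(crossprod(Zo, y - mean(y))) / n
  nz_prev <- Inf
  for (lambda in c(0.005, 0.02, 0.05, 0.2)) {
    m <- fit_enet(Zo, y, lambda, 1, standardize = FALSE)
    closed <- sign(rho) * pmax(abs(rho) - lambda, 0)
    expect_equal(m$beta, closed, tolerance = 1e-8)
    expect_lte(m$nonzero_count, nz_prev)
    nz_prev <- m$nonzero_count
  }
})

test_that("penalty limits recover least squares and ridge closed forms", {
  set.seed(6)
  n <- 60; k <- 6
  Z <- rand_cohort(n, k, seed = 6)
  y <- as.numeric(Z %*% rnorm(k)) + rnorm(n)
  # lambda -> 0: ordinary least squares (normal-equations oracle)
  m <- fit_enet(Z, y, 1e-10, 1, standardize = FALSE)
  ls <- lm.fit(cbind(1, Z), y)$coefficients
  expect_equal(m$beta, unname(ls[-1]), tolerance = 1e-4)
  expect_equal(m$intercept, unname(ls[1]), tolerance = 1e-4)

  # alpha near 0: ridge closed form on centered data within 2%
  lambda <- 0.5; alpha <- 0.001
  m2 <- fit_enet(Z, y, lambda, alpha, standardize = FALSE)
  Zc <- scale(Z, scale = FALSE)
  yc <- y - mean(y)
  ridge <- solve(crossprod(Zc) / n + lambda * (1 - alpha) * diag(k),
                 crossprod(Zc, yc) / n)
  expect_equal(m2$beta, as.numeric(ridge), tolerance = 0.02)
})

test_that("the in-package solver agrees with glmnet on the same objective", {
  # restricted to alpha = 1, where glmnet's lambda convention coincides with
  # the (1/2n)RSS + lambda*P_alpha objective; for alpha < 1 glmnet's internal
  # response scaling re-weights the L1/L2 mix, so the closed-form oracles
  # above are the reference instead
  set.seed(8)
  n <- 80; k <- 10
  Z <- rand_cohort(n, k, seed = 8)
  y <- as.numeric(Z[, 1] - 0.5 * Z[, 3]) + rnorm(n)
  for (lambda in c(0.02, 0.1, 0.5)) {
    m <- fit_enet(Z, y, lambda, 1, standardize = FALSE)
    g <- glmnet::glmnet(Z, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
    expect_equal(m$beta, as.numeric(g$beta), tolerance = 1e-6)
    expect_equal(m$intercept, as.numeric(g$a0), tolerance = 1e-6)
    expect_equal(m$nonzero_count, as.integer(g$df))
  }
})

test_that("prediction is linear, consistent and shape-checked", {
  Z <- rand_cohort(30, 5, seed = 9)
  y <- rnorm(30)
  m <- fit_enet(Z, y, 1e3, 1)   # fully shrunk
  expect_equal(predict(m, rand_cohort(7, 5)), rep(m$intercept, 7))
  m2 <- fit_enet(Z, y, 0.05, 0.5)
  f1 <- rand_cohort(1, 5, seed = 10); f2 <- rand_cohort(1, 5, seed = 11)
  a <- 0.3
  expect_equal(predict(m2, a * f1 + (1 - a) * f2),
               a * predict(m2, f1) + (1 - a) * predict(m2, f2),
               tolerance = 1e-10)
  # training residuals consistent with the stored objective
  resid <- y - predict(m2, Z)
  expect_equal(sum(resid^2) / (2 * 30) +
                 m2$lambda * sum((1 - m2$alpha) / 2 * m2$beta^2 +
                                   m2$alpha * abs(m2$beta)),
               m2$objective, tolerance = 1e-10)
  expect_error(predict(m2, rand_cohort(3, 4)), "columns")
})

test_that("R-squared and BIC follow their defining formulas", {
  y <- c(1, 2, 3, 4); yh <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, yh)$r2, 1 - 1 / 5)
  expect_equal(r_squared(y, y)$r2, 1)
  expect_equal(r_squared(y, rep(mean(y), 4))$r2, 0)
  expect_lt(r_squared(y, rev(y))$r2, 0)
  expect_error(r_squared(rep(1, 4), yh), "variance")

  set.seed(2)
  y <- rnorm(10); yh <- y + rnorm(10)
  rss <- sum((y - yh)^2)
  expect_equal(bic_score(y, yh, 3), 10 * log(rss / 10) + 3 * log(10))
  expect_lt(bic_score(y, yh, 5), bic_score(y, yh, 9))  # monotone in q
  # n = 10, RSS = 10, q = 0 -> 10 ln(1) + 0 = 0
  expect_equal(bic_score(rep(0, 10), rep(1, 10), 0), 0)
  expect_warning(b <- bic_score(y, y, 2), "RSS")
  expect_identical(b, -Inf)
  expect_error(bic_score(y, yh, 10), "n >")
})

test_that("path fits are order-independent within tolerance", {
  set.seed(12)
  Z <- scale(rand_cohort(40, 6, seed = 12))
  y <- rnorm(40)
  lams <- 10^seq(1, -3, length.out = 15)
  path <- connpred:::cpp_enet_path(Z, y, lams, 0.5, 1e-10, 100000L)
  for (i in c(3, 9, 15)) {
    single <- fit_enet(Z, y, lams[i], 0.5, standardize = FALSE)
    expect_equal(as.numeric(path$beta[, i]), single$beta, tolerance = 1e-8)
  }
})
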