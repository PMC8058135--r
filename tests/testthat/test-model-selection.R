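test_that("the default grid matches the canonical search space", {
  g <- hyper_grid()
  expect_length(g$k_values, 18)
  expect_equal(range(g$k_values), c(10, 95))
  expect_length(g$lambda_values, 100)
  expect_equal(range(g$lambda_values), c(1e-5, 1e5), tolerance = 1e-12)
  expect_equal(g$alpha_values, c(0.001, 0.25, 0.5, 0.75, 1))
  expect_error(hyper_grid(alpha_values = c(0, 1)), "alpha")
  expect_error(hyper_grid(lambda_values = c(-1, 1)), "lambda")
})

test_that("LOO selection enforces k <= n and finds planted linear signal", {
  lr <- lowrank_instance(n = 35, p = 80, k = 6, noise = 0.05, seed = 14)
  set.seed(14)
  y <- as.numeric(lr$F %*% c(1, -1, 0.5, 0, 0, 0)) + 0.3 * rnorm(35)
  g <- hyper_grid(k_values = c(4, 6, 10, 40),
                  lambda_values = 10^seq(-3, 1, length.out = 15),
                  alpha_values = c(0.001, 1))
  expect_warning(fbk <- pca_features_by_k(lr$X, c(4, 6, 10, 40)), "dropping")
  cv <- loo_select(fbk, y, g)
  expect_false(40 %in% cv$mse_table$k)      # k > n never evaluated
  expect_s3_class(cv, "cv_result")
  expect_gt(cv$pooled$r2, 0.6)
  expect_equal(cv$pooled$mse, mean((y - cv$pooled$predictions)^2))
  expect_equal(cv$pooled$r2, r_squared(y, cv$pooled$predictions)$r2)
  expect_lte(cv$pooled$nonzero_count, cv$best$k)

  # pooled predictions invariant to subject ordering
  perm <- sample(35)
  cv2 <- loo_select(lapply(fbk, function(F) F[perm, , drop = FALSE]),
                    y[perm], g)
  expect_equal(cv2$best, cv$best)
  expect_equal(cv2$pooled$predictions, cv$pooled$predictions[perm],
               tolerance = 1e-10)
})

test_that("nested LOO with a single-combination grid reduces to plain LOO", {
  lr <- lowrank_instance(n = 20, p = 30, k = 3, noise = 0.05, seed = 15)
  set.seed(15)
  y <- as.numeric(lr$F %*% c(1, -0.5, 0.25)) + 0.4 * rnorm(20)
  fbk <- pca_features_by_k(lr$X, 3)
  g1 <- hyper_grid(k_values = 3, lambda_values = 0.05, alpha_values = 0.5)
  cv <- loo_select(fbk, y, g1)
  for (rule in c("mean", "median", "mode")) {
    ncv <- nested_loo_select(fbk, y, g1, rule)
    expect_equal(ncv$best, list(k = 3, lambda = 0.05, alpha = 0.5))
    expect_equal(ncv$pooled$predictions, cv$pooled$predictions,
                 tolerance = 1e-6)
    expect_equal(ncv$aggregated$predictions, cv$pooled$predictions,
                 tolerance = 1e-6)
    expect_true(all(ncv$per_fold$k == 3))
  }
})

test_that("hyperparameter aggregation averages, snaps and breaks ties as documented", {
  g <- hyper_grid()
  sel <- data.frame(k = c(10, 10, 10, 95),
                    lambda = c(0.1, 0.1, 0.1, 0.1),
                    alpha = c(0.25, 0.25, 1, 1))
  expect_equal(aggregate_hyperparams(sel, "median", g)$k, 10)
  expect_equal(aggregate_hyperparams(sel, "mode", g)$k, 10)
  # mean k = 31.25 -> nearest grid value 30
  expect_equal(aggregate_hyperparams(sel, "mean", g)$k, 30)
  # mode tie on alpha {0.25 x2, 1 x2} -> smaller value
  expect_equal(aggregate_hyperparams(sel, "mode", g)$alpha, 0.25)
  expect_equal(aggregate_hyperparams(data.frame(k = c(10, 15, 95),
                                                lambda = 1, alpha = 1),
                                     "median", g)$k, 15)

  # lambda mean on the log10 scale, snapped in log distance
  sel2 <- data.frame(k = 10, lambda = c(1e-2, 1e-2, 1e2), alpha = 1)
  target <- 10^mean(log10(sel2$lambda))          # 10^(-2/3)
  lg <- g$lambda_values
  expect_equal(aggregate_hyperparams(sel2, "mean", g)$lambda,
               lg[which.min(abs(log10(lg) - log10(target)))])
})

test_that("median aggregation resists a planted outlier fold better than the mean", {
  # fold-wise selections with one outlier lambda; evaluate each aggregate by
  # full-sample LOO on cohorts with real signal
  g <- hyper_grid(k_values = 4, lambda_values = 10^seq(-3, 3, length.out = 30),
                  alpha_values = 1)
  wins <- 0L
  for (s in 1:20) {
    lr <- lowrank_instance(n = 25, p = 40, k = 4, noise = 0.05, seed = 100 + s)
    set.seed(100 + s)
    y <- as.numeric(lr$F %*% c(1, -0.8, 0.5, 0)) + 0.5 * rnorm(25)
    fbk <- pca_features_by_k(lr$X, 4)
    sel <- data.frame(k = 4, lambda = c(rep(0.05, 24), 1000), alpha = 1)
    r2_at <- function(agg) {
      pm <- connpred:::cpp_enet_loo(fbk[["4"]], y, agg$lambda, agg$alpha,
                                    1e-8, 100000L)
      r_squared(y, pm[, 1])$r2
    }
    if (r2_at(aggregate_hyperparams(sel, "median", g)) >=
        r2_at(aggregate_hyperparams(sel, "mean", g)) - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 12)  # >= 60% of replicates
})

test_that("Wilcoxon signed-rank matches exact enumeration and R's implementation", {
  # brute-force oracle: enumerate all sign assignments
  exact_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    p_le <- mean(vs <= v + 1e-12); p_ge <- mean(vs >= v - 1e-12)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(30)
  for (rep in 1:5) {
    d <- round(rnorm(6), 2)
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$p_value, exact_p(d), tolerance = 1e-12)
  }
  # ties and zeros handled; n = 8 with duplicated magnitudes
  d <- c(0.5, -0.5, 1.2, 1.2, -0.3, 2, 0, -1.2)
  expect_equal(wilcoxon_signed_rank(d)$p_value, exact_p(d), tolerance = 1e-12)
  # agreement with stats::wilcox.test in the clean exact case
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-sample normal path runs and is sane
  set.seed(32)
  wl <- wilcoxon_signed_rank(rnorm(60, mean = 0.8), rnorm(60))
  expect_identical(wl$method, "normal")
  expect_lt(wl$p_value, 0.01)
})

test_that("compare_models builds the Bonferroni-corrected pairwise table", {
  set.seed(33)
  res <- list(pca = rnorm(30), ica = rnorm(30), dl = rnorm(30),
              nnmf = rnorm(30) + 1.5)
  tab <- compare_models(res)
  expect_equal(nrow(tab), 6)                        # m = 6 pairs for 4 methods
  expect_equal(unique(tab$threshold), 0.05 / 6)
  expect_true(all(tab$significant == (tab$p_value < 0.05 / 6)))

  same <- list(a = res$pca, b = res$pca)
  expect_equal(compare_models(same)$p_value, 1)
  expect_error(compare_models(list(a = rnorm(5))), "two models")
  expect_error(compare_models(list(a = rnorm(5), b = rnorm(6))), "equal length")
})
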