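#' Standardize features with training statistics
#'
#' Columns are centered and scaled to unit standard deviation using the
#' training rows only; an optional apply set is transformed with the same
#' statistics (the leakage-safe convention for cross-validation). Constant
#' columns get sd 1 and are flagged.
#'
#' @param F_train n x k training feature matrix.
#' @param F_apply optional matrix to transform with the training statistics.
#' @return List with `Z_train`, `Z_apply` (or NULL) and `standardizer`
#'   (`means`, `sds`, `constant`).
#' @export
standardize_features <- function(F_train, F_apply = NULL) {
  F_train <- as.matrix(F_train)
  if (nrow(F_train) < 2L) stop("need at least 2 training rows", call. = FALSE)
  means <- colMeans(F_train)
  sds <- apply(F_train, 2L, stats::sd)
  constant <- sds <= 0
  sds[constant] <- 1
  st <- list(means = means, sds = sds, constant = constant)
  list(Z_train = scale_with(F_train, st),
       Z_apply = if (!is.null(F_apply)) scale_with(as.matrix(F_apply), st),
       standardizer = st)
}

#' @noRd
scale_with <- function(F, st) {
  sweep(sweep(F, 2L, st$means), 2L, st$sds, `/`)
}

#' Fit an elastic-net regression
#'
#' Minimizes (1/2n) sum_i (y_i - b0 - z_i' beta)^2 +
#' lambda sum_j ( (1-alpha)/2 beta_j^2 + alpha |beta_j| ) by cyclic
#' coordinate descent, with an unpenalized intercept. alpha = 1 is the
#' LASSO (exact zeros); alpha near 0 approaches ridge (alpha = 0 itself is
#' excluded). Features are standardized internally by default and the
#' coefficients are kept on the standardized scale; prediction applies the
#' stored standardizer.
#'
#' @param F n x k feature matrix (raw scale unless `standardize = FALSE`).
#' @param y numeric response, length n.
#' @param lambda penalty strength, >= 0.
#' @param alpha elastic-net mixing in (0, 1].
#' @param standardize standardize columns internally (default TRUE).
#' @param tol,max_iter coordinate-descent controls.
#' @return Object of class `enet_model`: `beta` (standardized scale),
#'   `intercept`, `lambda`, `alpha`, `nonzero_count`, `standardizer`,
#'   `objective`, `iterations`.
#' @export
fit_enet <- function(F, y, lambda, alpha, standardize = TRUE,
                     tol = 1e-9, max_iter = 100000L) {
  F <- as.matrix(F)
  y <- as.numeric(y)
  if (nrow(F) != length(y)) stop("rows of F must match length of y", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (standardize) {
    s <- standardize_features(F)
    Z <- s$Z_train; st <- s$standardizer
  } else {
    Z <- F
    st <- list(means = rep(0, ncol(F)), sds = rep(1, ncol(F)),
               constant = rep(FALSE, ncol(F)))
  }
  fit <- cpp_enet_path(Z, y, lambda, alpha, tol, as.integer(max_iter))
  beta <- as.numeric(fit$beta[, 1L])
  b0 <- fit$intercept[1L]
  resid <- y - b0 - as.numeric(Z %*% beta)
  obj <- sum(resid^2) / (2 * length(y)) +
    lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
  structure(list(beta = beta, intercept = b0, lambda = lambda, alpha = alpha,
                 nonzero_count = sum(beta != 0), standardizer = st,
                 objective = obj, iterations = fit$iterations[1L]),
            class = "enet_model")
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf("<enet_model> k = %d, lambda = %.4g, alpha = %.3g, nonzero = %d\n",
              length(x$beta), x$lambda, x$alpha, x$nonzero_count))
  invisible(x)
}

#' Predict from an elastic-net model
#'
#' @param object an `enet_model`.
#' @param newdata matrix of raw features with k columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.enet_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop(sprintf("newdata has %d columns, model expects %d",
                 ncol(newdata), length(object$beta)), call. = FALSE)
  Z <- scale_with(newdata, object$standardizer)
  as.numeric(object$intercept + Z %*% object$beta)
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2). Can be negative for
#' predictions worse than the mean (e.g. pooled cross-validated predictions
#' under a null). The MSE of the predictions is returned alongside.
#'
#' @param y observed scores. @param y_hat predicted scores.
#' @return List with `r2` and `mse`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2L)
    stop("y and y_hat must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("y has zero variance; R^2 undefined", call. = FALSE)
  ss_res <- sum((y - y_hat)^2)
  list(r2 = 1 - ss_res / ss_tot, mse = mean((y - y_hat)^2))
}

#' Bayesian information criterion for a fitted regression
#'
#' Gaussian-likelihood form BIC = n log(RSS/n) + q log(n), where q counts
#' only the non-zero coefficients (the intercept is not counted). Lower is
#' better.
#'
#' @param y observed scores. @param y_hat predictions.
#' @param nonzero_count number of non-zero coefficients q.
#' @param n sample size (defaults to length(y)).
#' @return Scalar BIC; a perfect fit (RSS = 0) returns -Inf with a warning.
#' @export
bic_score <- function(y, y_hat, nonzero_count, n = length(y)) {
  if (n <= nonzero_count)
    stop("BIC requires n > nonzero_count", call. = FALSE)
  rss <- sum((y - y_hat)^2)
  if (rss <= 0) {
    warning("RSS = 0; BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + nonzero_count * log(n)
}

#' Serialize a regression model
#'
#' Writes a JSON file with the scalar fields and a delimited coefficient
#' table (feature, standardized beta, raw-scale beta).
#'
#' @param model an `enet_model`. @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_enet_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(lambda = model$lambda, alpha = model$alpha,
                            intercept = model$intercept,
                            nonzero_count = model$nonzero_count,
                            objective = model$objective),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(data.frame(feature = seq_along(model$beta),
                         beta_standardized = model$beta,
                         beta_raw = model$beta / model$standardizer$sds),
              file.path(dir, "coefficients.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
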