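#' Experiment configuration
#'
#' Declarative description of one end-to-end experiment: the data source
#' (synthetic generator config, or cohort/atlas/score files), the feature
#' extraction methods, the hyperparameter grid, the cross-validation scheme
#' and the methodological flags. The config is serialized verbatim into the
#' run manifest so any result table can be regenerated from cohort +
#' manifest alone.
#'
#' @param synthetic a [synth_config()], or NULL to load files.
#' @param cohort_file,atlas_file,scores_file input paths (used when
#'   `synthetic` is NULL).
#' @param score_domain cognitive domain to extract from the scores file.
#' @param methods feature extraction methods to run.
#' @param grid a [hyper_grid()].
#' @param scheme `"loo"` or `"nested_loo"`.
#' @param aggregation central-tendency rule for nested LOO.
#' @param fit_scope `"full"` fits extraction on the whole cohort including
#'   unscored subjects (the study design this mirrors); `"scored"` restricts
#'   extraction to scored subjects (leakage-safe variant).
#' @param negativity_policy NNMF policy for negative edges.
#' @param dl_sparsity dictionary-learning L1 penalty.
#' @param n_top edges kept in ranked map tables.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir directory for result files, or NULL to skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, cohort_file = NULL, atlas_file = NULL,
                       scores_file = NULL, score_domain = NULL,
                       methods = c("pca", "ica", "dl", "nnmf"),
                       grid = hyper_grid(), scheme = c("loo", "nested_loo"),
                       aggregation = "median", fit_scope = c("full", "scored"),
                       negativity_policy = "shift", dl_sparsity = 1,
                       n_top = 200L, seed = 1L, output_dir = NULL) {
  scheme <- match.arg(scheme)
  fit_scope <- match.arg(fit_scope)
  methods <- match.arg(methods, c("pca", "ica", "dl", "nnmf"), several.ok = TRUE)
  if (is.null(synthetic) && (is.null(cohort_file) || is.null(scores_file)))
    stop("either a synthetic config or cohort_file + scores_file is required",
         call. = FALSE)
  structure(list(synthetic = synthetic, cohort_file = cohort_file,
                 atlas_file = atlas_file, scores_file = scores_file,
                 score_domain = score_domain, methods = methods, grid = grid,
                 scheme = scheme, aggregation = aggregation,
                 fit_scope = fit_scope, negativity_policy = negativity_policy,
                 dl_sparsity = dl_sparsity, n_top = as.integer(n_top),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Fit one extraction method over a k grid
#'
#' PCA is fitted once at the largest k and truncated; the stochastic
#' methods are refitted per k with seeds derived from `seed`.
#'
#' @param X [cohort_table()] or matrix.
#' @param method extraction method.
#' @param k_values integer k grid (values above n - 1 dropped with warning).
#' @param seed base seed.
#' @param ... method-specific arguments.
#' @return Named list (k as character) of `feature_model`s.
#' @export
extract_feature_sets <- function(X, method, k_values, seed = 1L, ...) {
  Xm <- as_cohort_matrix(X)
  n <- nrow(Xm)
  ok <- k_values <= n - 1L
  if (!all(ok)) {
    warning(sprintf("dropping %d k value(s) above n - 1", sum(!ok)))
    k_values <- k_values[ok]
  }
  k_values <- sort(unique(as.integer(k_values)))
  if (!length(k_values)) stop("no usable k values", call. = FALSE)
  if (method == "pca") {
    full <- fit_pca(Xm, max(k_values))
    models <- lapply(k_values, function(k) truncate_features(full, k))
  } else {
    models <- lapply(seq_along(k_values), function(ik)
      fit_features(Xm, method, k_values[ik], seed = seed + ik, ...))
  }
  stats::setNames(models, as.character(k_values))
}

#' Run the full experiment
#'
#' Executes extraction, the reconstruction-error curve, per-method
#' hyperparameter selection, pairwise model comparison and map
#' back-projection, and (when `output_dir` is set) writes the result
#' tables, per-method maps, a Wilcoxon table and a JSON manifest. The same
#' config and seed always reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("extract", "select", "compare", "maps")`;
#'   later stages imply the earlier ones they need.
#' @return List with `results` (Table-style data frame: method, scheme,
#'   aggregation, r2, mse, bic, lambda, alpha, k, nz), `error_curve`,
#'   `selection` (per-method `cv_result`), `comparison`, `maps`,
#'   `map_correlations`, `atlas`, `config`.
#' @export
run_experiment <- function(config,
                           stages = c("extract", "select", "compare", "maps")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  # ---- data ----
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- config$seed
    sim <- generate_cohort(sc)
    cohort <- sim$cohort; scores <- sim$scores
  } else {
    atlas <- if (!is.null(config$atlas_file)) read_atlas(config$atlas_file)
    cohort <- load_cohort(config$cohort_file, atlas = atlas, quiet = TRUE)
    scores <- read_scores(config$scores_file, config$score_domain)
    sim <- NULL
  }
  aligned <- align_scores(cohort, scores)
  scored_idx <- match(aligned$subject_ids, cohort$subject_ids)
  X_fit <- if (config$fit_scope == "full") cohort$X else aligned$X

  # ---- extraction + error curve ----
  models <- list()
  for (m in config$methods) {
    extra <- switch(m,
                    dl = list(dl_sparsity = config$dl_sparsity),
                    nnmf = list(negativity_policy = config$negativity_policy),
                    list())
    models[[m]] <- do.call(extract_feature_sets,
                           c(list(X_fit, m, config$grid$k_values,
                                  seed = config$seed + 100L * match(m, config$methods)),
                             extra))
  }
  curve <- do.call(rbind, lapply(config$methods, function(m)
    data.frame(method = m, k = as.integer(names(models[[m]])),
               mse = vapply(models[[m]],
                            function(fm) reconstruction_error(fm, X_fit),
                            numeric(1)))))
  rownames(curve) <- NULL
  out <- list(error_curve = curve, atlas = cohort$atlas, config = config,
              truth = if (!is.null(sim)) sim$truth)
  if (!any(c("select", "compare", "maps") %in% stages)) {
    write_experiment(out, config)
    return(invisible(out))
  }

  # ---- selection ----
  selection <- list()
  for (m in config$methods) {
    fbk <- lapply(models[[m]], function(fm) {
      Fk <- fm$F_train
      if (config$fit_scope == "full") Fk[scored_idx, , drop = FALSE] else Fk
    })
    selection[[m]] <- if (config$scheme == "loo")
      loo_select(fbk, aligned$y, config$grid)
    else
      nested_loo_select(fbk, aligned$y, config$grid,
                        aggregation = config$aggregation)
  }
  out$selection <- selection
  out$results <- do.call(rbind, lapply(config$methods, function(m) {
    cv <- selection[[m]]
    data.frame(method = m, scheme = cv$scheme, aggregation = cv$aggregation,
               r2 = cv$pooled$r2, mse = cv$pooled$mse, bic = cv$pooled$bic,
               lambda = cv$best$lambda, alpha = cv$best$alpha, k = cv$best$k,
               nz = cv$pooled$nonzero_count)
  }))

  # ---- comparison ----
  if ("compare" %in% stages && length(config$methods) >= 2L)
    out$comparison <- compare_models(selection)

  # ---- maps ----
  if ("maps" %in% stages) {
    maps <- lapply(config$methods, function(m) {
      cv <- selection[[m]]
      mp <- back_project(models[[m]][[as.character(cv$best$k)]], cv$model)
      mp$atlas <- cohort$atlas
      mp
    })
    names(maps) <- config$methods
    out$maps <- maps
    if (length(maps) >= 2L) {
      cm <- diag(1, length(maps))
      dimnames(cm) <- list(names(maps), names(maps))
      for (i in seq_along(maps)) for (j in seq_along(maps))
        if (i != j)
          cm[i, j] <- if (stats::sd(maps[[i]]$edge_weights) == 0 ||
                          stats::sd(maps[[j]]$edge_weights) == 0)
            NA_real_ else map_correlation(maps[[i]], maps[[j]])
      out$map_correlations <- cm
    }
  }
  write_experiment(out, config)
  invisible(out)
}

#' @noRd
write_experiment <- function(out, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, ...) write.table(x, file.path(dir, f), sep = "\t",
                                        quote = FALSE, row.names = FALSE, ...)
  wt(out$error_curve, "error_curve.tsv")
  if (!is.null(out$results)) wt(out$results, "results.tsv")
  if (!is.null(out$comparison)) wt(out$comparison, "wilcoxon.tsv")
  if (!is.null(out$maps))
    for (m in names(out$maps))
      write_predictive_map(out$maps[[m]], file.path(dir, paste0("map_", m)),
                           atlas = out$atlas, n_top = config$n_top)
  if (!is.null(out$map_correlations))
    write.table(out$map_correlations, file.path(dir, "map_correlations.tsv"),
                sep = "\t", quote = FALSE)
  cfg <- unclass(config)
  cfg$grid <- unclass(cfg$grid)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  cfg$output_dir <- NULL
  jsonlite::write_json(list(config = cfg,
                            package_version = as.character(utils::packageVersion("connpred"))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Human-readable experiment summary
#'
#' @param out the list returned by [run_experiment()].
#' @param file optional path to also write the summary to.
#' @return Invisibly, the summary lines.
#' @export
report_experiment <- function(out, file = NULL) {
  lines <- c("Elastic-net regression on extracted connectivity features",
             strrep("-", 60))
  if (!is.null(out$results)) {
    tab <- out$results
    lines <- c(lines,
               sprintf("%-6s %-10s %6s %6s %8s %8s %6s %4s %4s",
                       "method", "scheme", "R2", "MSE", "BIC", "lambda",
                       "alpha", "k", "NZ"),
               sprintf("%-6s %-10s %6.3f %6.3f %8.2f %8.4f %6.3f %4d %4d",
                       tab$method, tab$scheme, tab$r2, tab$mse, tab$bic,
                       tab$lambda, tab$alpha, tab$k, tab$nz))
  }
  if (!is.null(out$map_correlations)) {
    lines <- c(lines, "", "Predictive-map correlations:",
               utils::capture.output(print(round(out$map_correlations, 3))))
  }
  if (!is.null(out$comparison)) {
    ns <- sum(out$comparison$significant)
    lines <- c(lines, "",
               sprintf("Wilcoxon signed-rank on squared residuals: %d of %d pairs significant at Bonferroni threshold %.4g",
                       ns, nrow(out$comparison), out$comparison$threshold[1]))
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
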