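#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of subjects whose vectorized connectivity edges follow
#' the low-rank model X = F W' + noise, with network-block structured
#' loadings W and behavioural scores generated linearly from a subset of the
#' latent components. This is the data-generating world the analysis
#' pipeline assumes, with full ground truth retained for recovery tests.
#'
#' Defaults are desk-scale: P = 64 parcels (p = 2016 edges), n = 100
#' subjects, k_true = 10 latent components of which 3 carry behavioural
#' signal. Edge noise defaults to signal-to-noise ratio 2 (mean per-edge
#' signal variance over noise variance), and score noise to a noiseless
#' score R-squared of 0.6.
#'
#' @param P parcels. @param n subjects. @param k_true latent components.
#' @param M networks. @param n_predictive components with non-zero
#'   behavioural coefficient (<= k_true).
#' @param noise_sd edge noise standard deviation; `NULL` derives it from
#'   `edge_snr`.
#' @param edge_snr target mean per-edge signal-to-noise variance ratio,
#'   used only when `noise_sd` is `NULL`.
#' @param score_noise_sd score noise standard deviation; `NULL` derives it
#'   from `target_r2`.
#' @param target_r2 population R-squared of the score model, used only when
#'   `score_noise_sd` is `NULL`.
#' @param frac_unscored fraction of subjects with missing score (the study
#'   design this emulates had scores for 95 of 100 subjects).
#' @param b_scale multiplier on the behavioural coefficients; 0 gives a
#'   pure-noise (null) score with no connectivity signal, in which case
#'   `score_noise_sd` must be given explicitly.
#' @param nonnegative if `TRUE`, loadings, latent scores and noise are all
#'   nonnegative (half-normal), so X >= 0 natively.
#' @param intercept_true intercept of the score model.
#' @param seed integer seed; every draw flows from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(P = 64, n = 100, k_true = 10, M = 8,
                         n_predictive = 3, noise_sd = NULL, edge_snr = 2,
                         score_noise_sd = NULL, target_r2 = 0.6,
                         frac_unscored = 0.05, nonnegative = FALSE,
                         intercept_true = 0, b_scale = 1, seed = 1L) {
  p <- n_edges(P)
  if (k_true >= min(n, p))
    stop("k_true must be smaller than min(n, p)", call. = FALSE)
  if (n_predictive < 1L || n_predictive > k_true)
    stop("n_predictive must be in 1..k_true", call. = FALSE)
  if (M < 1L || M > P) stop("M must be in 1..P", call. = FALSE)
  b <- b_scale * rep_len(c(1, -0.8, 0.6, -0.5, 0.4), n_predictive)
  if (is.null(noise_sd)) noise_sd <- sqrt(k_true / (p * edge_snr))
  if (is.null(score_noise_sd)) {
    if (sum(b^2) == 0)
      stop("score_noise_sd must be given explicitly when b_scale = 0",
           call. = FALSE)
    score_noise_sd <- sqrt(sum(b^2) * (1 - target_r2) / target_r2)
  }
  structure(list(P = P, p = p, n = n, k_true = k_true, M = M,
                 n_predictive = n_predictive, noise_sd = noise_sd,
                 score_noise_sd = score_noise_sd, frac_unscored = frac_unscored,
                 nonnegative = nonnegative, intercept_true = intercept_true,
                 b_pattern = b, seed = as.integer(seed)),
            class = "synth_config")
}

#' Synthetic parcel atlas
#'
#' Parcels are assigned to M networks in contiguous blocks (as in sorted
#' connectivity matrices); coordinates are placed on a unit sphere for
#' export only.
#'
#' @param config a [synth_config()].
#' @return A [parcel_atlas()].
#' @export
synth_atlas <- function(config) {
  P <- config$P; M <- config$M
  net <- rep(sprintf("net_%02d", seq_len(M)), each = ceiling(P / M))[seq_len(P)]
  theta <- 2 * pi * (seq_len(P) - 1) / P
  phi <- acos(1 - 2 * (seq_len(P) - 0.5) / P)
  co <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  parcel_atlas(sprintf("parcel_%03d", seq_len(P)), net, co)
}

#' Network-block structured loading matrix
#'
#' Each latent component concentrates its squared mass on the edges of 1 to
#' 3 randomly chosen network-pair blocks (within- or between-network), over
#' a small dense background, and is scaled to unit Euclidean norm. With
#' `nonnegative = TRUE` all entries are >= 0.
#'
#' @param config a [synth_config()].
#' @param atlas atlas to take network labels from; defaults to
#'   [synth_atlas()].
#' @return p x k_true numeric matrix with unit-norm columns and an attribute
#'   `blocks` listing each column's designated network pairs.
#' @export
make_loadings <- function(config, atlas = synth_atlas(config)) {
  stopifnot(inherits(config, "synth_config"))
  ei <- edge_index(config$P)
  net <- as.integer(atlas$network_label)
  enet_i <- net[ei$i]; enet_j <- net[ei$j]
  block_id <- paste(pmin(enet_i, enet_j), pmax(enet_i, enet_j))
  all_blocks <- unique(block_id)
  p <- config$p; k <- config$k_true
  W <- matrix(0, p, k)
  blocks <- vector("list", k)
  for (c in seq_len(k)) {
    nb <- sample(1:3, 1L)
    chosen <- sample(all_blocks, min(nb, length(all_blocks)))
    blocks[[c]] <- chosen
    inblk <- block_id %in% chosen
    w <- rnorm(p, sd = 0.05)        # dense background
    w[inblk] <- rnorm(sum(inblk), sd = 1)
    if (config$nonnegative) w <- abs(w)
    W[, c] <- w / sqrt(sum(w^2))
  }
  attr(W, "blocks") <- blocks
  W
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws latent subject scores F (standard normal, or half-normal in
#' nonnegative mode), builds X = F W' + noise_sd * E, and behavioural
#' scores y = intercept + F b + score_noise_sd * eps, with b non-zero on the
#' first `n_predictive` components and signed so that deficits are negative.
#' A fraction of subjects is flagged unscored (NA). Fully reproducible from
#' the config seed.
#'
#' @param config a [synth_config()].
#' @return List with `cohort` (a [cohort_table()]), `scores` (named numeric,
#'   NA = unscored) and `truth`: `W_true`, `F_true`, `b_true`,
#'   `intercept_true`, `m_true = W_true %*% b_true`, `realized_r2` (the
#'   score R-squared actually realized in this draw) and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  atlas <- synth_atlas(config)
  W <- make_loadings(config, atlas)
  n <- config$n; p <- config$p; k <- config$k_true
  F_true <- matrix(rnorm(n * k), n, k)
  E <- matrix(rnorm(n * p), n, p)
  if (config$nonnegative) { F_true <- abs(F_true); E <- abs(E) }
  X <- F_true %*% t(W) + config$noise_sd * E
  b <- c(config$b_pattern, rep(0, k - config$n_predictive))
  y_signal <- config$intercept_true + as.numeric(F_true %*% b)
  y <- y_signal + config$score_noise_sd * rnorm(n)
  ids <- sprintf("sub_%03d", seq_len(n))
  scores <- stats::setNames(y, ids)
  n_miss <- floor(config$frac_unscored * n)
  if (n_miss > 0) scores[sample(n, n_miss)] <- NA
  realized_r2 <- r_squared(y, y_signal)$r2
  cohort <- suppressWarnings(cohort_table(X, ids, atlas))
  list(cohort = cohort, scores = scores,
       truth = list(W_true = W, F_true = F_true, b_true = b,
                    intercept_true = config$intercept_true,
                    m_true = as.numeric(W %*% b),
                    realized_r2 = realized_r2, config = config))
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the cohort, atlas and scores in the delimited formats the loaders
#' read, plus the ground-truth arrays and a JSON manifest (config + seed).
#'
#' @param sim output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             atlas = file.path(dir, "atlas.tsv"),
             scores = file.path(dir, "scores.tsv"),
             W_true = file.path(dir, "W_true.tsv"),
             b_true = file.path(dir, "b_true.tsv"),
             m_true = file.path(dir, "m_true.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write.table(data.frame(subject_id = sim$cohort$subject_ids, sim$cohort$X,
                         check.names = FALSE),
              paths["cohort"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(sim$cohort$atlas), paths["atlas"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(subject_id = names(sim$scores), domain = "synthetic",
                         score = unname(sim$scores)),
              paths["scores"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$W_true, paths["W_true"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(component = seq_along(sim$truth$b_true),
                         b = sim$truth$b_true),
              paths["b_true"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(edge = seq_along(sim$truth$m_true),
                         weight = sim$truth$m_true),
              paths["m_true"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$truth$config)
  jsonlite::write_json(c(cfg, list(realized_r2 = sim$truth$realized_r2)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
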