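#' Back-project regression coefficients into edge space
#'
#' Rescales the standardized-scale coefficients to the raw feature scale
#' (beta_raw_j = beta_j / sd_j) and pushes them through the extraction
#' weights: the analysis forward map when the method has one (PCA, ICA),
#' otherwise the synthesis basis/dictionary (DL, NNMF). For PCA/ICA the
#' resulting edge map is prediction-equivalent: (x - center) . m plus the
#' adjusted intercept reproduces the feature-space prediction exactly.
#'
#' @param fm a fitted `feature_model`.
#' @param rm a fitted `enet_model` with matching k.
#' @param transform_source `"auto"` (forward map if present, else basis),
#'   `"forward_map"` or `"basis"`.
#' @return Object of class `predictive_map`: `edge_weights` (length p),
#'   `matrix` (symmetric P x P if the edge count matches an integer P),
#'   `intercept` (adjusted for centering/standardization), `atlas`,
#'   `provenance`.
#' @export
back_project <- function(fm, rm, transform_source = c("auto", "forward_map", "basis")) {
  transform_source <- match.arg(transform_source)
  stopifnot(inherits(fm, "feature_model"), inherits(rm, "enet_model"))
  if (fm$k != length(rm$beta))
    stop("feature model and regression model disagree on k", call. = FALSE)
  if (transform_source == "auto")
    transform_source <- if (!is.null(fm$forward_map)) "forward_map" else "basis"
  Tm <- switch(transform_source, forward_map = fm$forward_map, basis = fm$basis)
  if (is.null(Tm))
    stop(sprintf("feature model has no %s", transform_source), call. = FALSE)
  beta_raw <- rm$beta / rm$standardizer$sds
  m <- as.numeric(Tm %*% beta_raw)
  intercept <- rm$intercept - sum(beta_raw * rm$standardizer$means)
  p <- length(m)
  P <- (1 + sqrt(1 + 8 * p)) / 2
  mat <- if (P == round(P)) restore_symmetric(m, as.integer(P)) else NULL
  structure(list(edge_weights = m, matrix = mat, intercept = intercept,
                 center = fm$center, atlas = attr(fm, "atlas"),
                 provenance = list(method = fm$method, k = fm$k,
                                   lambda = rm$lambda, alpha = rm$alpha,
                                   transform_source = transform_source)),
            class = "predictive_map")
}

#' @export
print.predictive_map <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("<predictive_map> %s (k = %d, lambda = %.4g, alpha = %.3g) via %s; %d edges, %d non-zero\n",
              pr$method, pr$k, pr$lambda, pr$alpha, pr$transform_source,
              length(x$edge_weights), sum(x$edge_weights != 0)))
  invisible(x)
}

#' Predict behavioural scores directly from edge space
#'
#' @param object a `predictive_map`.
#' @param newdata n x p matrix of edge vectors.
#' @param ... unused.
#' @return Numeric predictions; exact for PCA/ICA-derived maps.
#' @export
predict.predictive_map <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xc <- sweep(newdata, 2L, object$center)
  as.numeric(object$intercept + Xc %*% object$edge_weights)
}

#' Top edges of a predictive map
#'
#' Ranks edges by absolute weight (descending; ties by ascending edge index)
#' and returns the strongest N with their parcel pair, networks (when an
#' atlas is available) and sign.
#'
#' @param map a `predictive_map`.
#' @param n_top number of edges to keep (default 200).
#' @param atlas optional [parcel_atlas()] used to annotate parcels.
#' @return Data frame: `rank`, `edge`, `parcel_i`, `parcel_j`, `network_i`,
#'   `network_j`, `weight`, `sign`.
#' @export
top_edges <- function(map, n_top = 200L, atlas = map$atlas) {
  w <- map$edge_weights
  p <- length(w)
  if (n_top > p) stop("n_top exceeds the number of edges", call. = FALSE)
  ord <- order(-abs(w), seq_along(w))[seq_len(n_top)]
  P <- (1 + sqrt(1 + 8 * p)) / 2
  ei <- edge_index(as.integer(round(P)))
  out <- data.frame(rank = seq_len(n_top), edge = ord,
                    parcel_i = ei$i[ord], parcel_j = ei$j[ord],
                    weight = w[ord], sign = sign(w[ord]))
  if (!is.null(atlas)) {
    out$network_i <- as.character(atlas$network_label[out$parcel_i])
    out$network_j <- as.character(atlas$network_label[out$parcel_j])
    out$name_i <- atlas$parcel_name[out$parcel_i]
    out$name_j <- atlas$parcel_name[out$parcel_j]
  }
  out
}

#' Correlation between two predictive maps
#'
#' Pearson correlation of the edge-weight vectors.
#'
#' @param a,b `predictive_map` objects (or plain edge-weight vectors) over
#'   the same edge set.
#' @return Scalar correlation in [-1, 1].
#' @export
map_correlation <- function(a, b) {
  wa <- if (inherits(a, "predictive_map")) a$edge_weights else as.numeric(a)
  wb <- if (inherits(b, "predictive_map")) b$edge_weights else as.numeric(b)
  if (length(wa) != length(wb))
    stop("maps are over different edge sets", call. = FALSE)
  if (stats::sd(wa) == 0 || stats::sd(wb) == 0)
    stop("zero-variance map; correlation undefined", call. = FALSE)
  stats::cor(wa, wb)
}

#' Per-parcel contribution to a predictive map
#'
#' For each parcel, the sum of absolute weights of the selected edges
#' incident to it, normalized so the strongest parcel scores 1 (node sizes
#' in connectome renderings are drawn proportional to this).
#'
#' @param edges output of [top_edges()].
#' @param P total parcel count; inferred from the edge table if missing.
#' @return Data frame `parcel`, `contribution` (raw sum), `score`
#'   (normalized to max 1), sorted by parcel.
#' @export
node_contribution <- function(edges, P = max(edges$parcel_i, edges$parcel_j)) {
  if (nrow(edges) == 0L) stop("empty edge table", call. = FALSE)
  contrib <- numeric(P)
  aw <- abs(edges$weight)
  for (r in seq_len(nrow(edges))) {
    contrib[edges$parcel_i[r]] <- contrib[edges$parcel_i[r]] + aw[r]
    contrib[edges$parcel_j[r]] <- contrib[edges$parcel_j[r]] + aw[r]
  }
  data.frame(parcel = seq_len(P), contribution = contrib,
             score = if (max(contrib) > 0) contrib / max(contrib) else contrib)
}

#' Network-block summary of a predictive map
#'
#' Mean absolute edge weight within every pair of networks (within- and
#' between-network blocks), as a symmetric M x M matrix. Quantifies which
#' large-scale circuits carry the predictive signal.
#'
#' @param map a `predictive_map`.
#' @param atlas a [parcel_atlas()] with network labels for the map's P.
#' @return Symmetric M x M matrix with network labels as dimnames.
#' @export
network_block_summary <- function(map, atlas = map$atlas) {
  if (is.null(atlas)) stop("an atlas with network labels is required", call. = FALSE)
  P <- n_parcels(atlas)
  if (n_edges(P) != length(map$edge_weights))
    stop("atlas does not match the map's edge count", call. = FALSE)
  ei <- edge_index(P)
  net <- as.integer(atlas$network_label)
  M <- nlevels(atlas$network_label)
  a <- pmin(net[ei$i], net[ei$j])
  b <- pmax(net[ei$i], net[ei$j])
  aw <- abs(map$edge_weights)
  out <- matrix(0, M, M, dimnames = list(levels(atlas$network_label),
                                         levels(atlas$network_label)))
  for (ia in seq_len(M)) for (ib in ia:M) {
    sel <- a == ia & b == ib
    val <- if (any(sel)) mean(aw[sel]) else 0
    out[ia, ib] <- val
    out[ib, ia] <- val
  }
  out
}

#' Export a predictive map to delimited files
#'
#' Writes the square matrix, the ranked edge table, the network-block
#' summary and an optional node file (parcel, coordinates, contribution)
#' consumable by external connectome viewers.
#'
#' @param map a `predictive_map`. @param dir output directory.
#' @param atlas optional atlas for annotation.
#' @param n_top edges to keep in the ranked table.
#' @return Invisibly, the written paths.
#' @export
write_predictive_map <- function(map, dir, atlas = map$atlas, n_top = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_top <- min(n_top, length(map$edge_weights))
  paths <- c(matrix = file.path(dir, "map_matrix.tsv"),
             edges = file.path(dir, "top_edges.tsv"))
  write.table(map$matrix, paths["matrix"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  te <- top_edges(map, n_top, atlas = atlas)
  write.table(te, paths["edges"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(atlas)) {
    paths["blocks"] <- file.path(dir, "network_blocks.tsv")
    write.table(network_block_summary(map, atlas), paths["blocks"],
                sep = "\t", quote = FALSE)
    nc <- node_contribution(te, P = n_parcels(atlas))
    if (all(c("x", "y", "z") %in% names(atlas)))
      nc <- cbind(nc, atlas[, c("x", "y", "z")])
    paths["nodes"] <- file.path(dir, "nodes.tsv")
    write.table(nc, paths["nodes"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
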