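#' Parcel atlas
#'
#' A parcellation table assigning each cortical parcel to one large-scale
#' intrinsic network. Parcels are indexed 1..P with no gaps; optional 3-D
#' coordinates are carried along for export to connectome viewers only and
#' are never used in computation.
#'
#' @param parcel_name character vector of parcel names (length P).
#' @param network_label character or factor of network memberships, same
#'   length; at least one network.
#' @param coordinates optional P x 3 numeric matrix of parcel coordinates
#'   (arbitrary units).
#' @return An object of class `parcel_atlas`: a data frame with columns
#'   `parcel_id`, `parcel_name`, `network_label` (factor) and optionally
#'   `x`, `y`, `z`.
#' @export
parcel_atlas <- function(parcel_name, network_label, coordinates = NULL) {
  P <- length(parcel_name)
  if (P < 2L) stop("an atlas needs at least 2 parcels", call. = FALSE)
  if (length(network_label) != P)
    stop("network_label must have one entry per parcel", call. = FALSE)
  at <- data.frame(
    parcel_id = seq_len(P),
    parcel_name = as.character(parcel_name),
    network_label = factor(network_label),
    stringsAsFactors = FALSE
  )
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != P || ncol(coordinates) != 3L)
      stop("coordinates must be a P x 3 matrix", call. = FALSE)
    at$x <- coordinates[, 1]; at$y <- coordinates[, 2]; at$z <- coordinates[, 3]
  }
  class(at) <- c("parcel_atlas", "data.frame")
  at
}

#' Number of parcels in an atlas
#' @param atlas a [parcel_atlas()].
#' @return Integer parcel count P.
#' @export
n_parcels <- function(atlas) nrow(atlas)

#' Number of unique edges for P parcels
#' @param P integer parcel count.
#' @return P(P-1)/2, the length of the vectorized upper triangle.
#' @export
n_edges <- function(P) as.integer(P * (P - 1) / 2)

#' Canonical edge ordering
#'
#' Enumerates the unique parcel pairs (i, j), i < j, in row-major upper
#' triangle order: (1,2), (1,3), ..., (1,P), (2,3), ... This is the fixed
#' convention used by [vectorize_connectome()] and all edge-space outputs.
#'
#' @param P integer parcel count.
#' @return Data frame with columns `edge`, `i`, `j` (1-based parcel ids).
#' @export
edge_index <- function(P) {
  i <- rep.int(seq_len(P - 1), (P - 1):1)
  j <- sequence((P - 1):1, from = 2:P)
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Construct a single-subject connectome matrix
#'
#' @param values P x P numeric matrix, correlation-like and symmetric within
#'   `tol`. The diagonal is ignored by all downstream computation.
#' @param atlas optional [parcel_atlas()] with matching P.
#' @param tol asymmetry tolerance.
#' @param force if `TRUE`, a matrix asymmetric beyond `tol` is symmetrized
#'   as (m + t(m))/2 instead of raising an error.
#' @return Object of class `connectome_matrix`.
#' @export
connectome_matrix <- function(values, atlas = NULL, tol = 1e-8, force = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (any(!is.finite(values)))
    stop("connectome matrix contains non-finite entries", call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    if (!force)
      stop(sprintf("matrix asymmetric beyond tolerance (max |m - t(m)| = %.3g); use force = TRUE to symmetrize", asym),
           call. = FALSE)
    values <- (values + t(values)) / 2
  }
  if (!is.null(atlas) && n_parcels(atlas) != nrow(values))
    stop("atlas parcel count does not match matrix dimension", call. = FALSE)
  structure(list(values = values, atlas = atlas),
            class = "connectome_matrix")
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in the canonical row-major edge order
#' (see [edge_index()]), discarding the diagonal and lower triangle. A
#' 324-parcel matrix yields 52,326 edge values.
#'
#' @param m a `connectome_matrix` or a plain symmetric numeric matrix.
#' @inheritParams connectome_matrix
#' @return Numeric vector of length P(P-1)/2 with attribute `P`.
#' @export
vectorize_connectome <- function(m, tol = 1e-8, force = FALSE) {
  if (!inherits(m, "connectome_matrix")) m <- connectome_matrix(m, tol = tol, force = force)
  v <- t(m$values)[lower.tri(m$values)]  # row-major upper triangle
  attr(v, "P") <- nrow(m$values)
  v
}

#' Restore an edge vector to a symmetric matrix
#'
#' Inverse of [vectorize_connectome()]: places the edge values back on the
#' upper and lower triangles and sets the diagonal to 0, so the roundtrip
#' `vectorize_connectome(restore_symmetric(v, P))` is exact.
#'
#' @param v numeric edge vector of length P(P-1)/2.
#' @param P integer parcel count.
#' @return P x P symmetric numeric matrix with zero diagonal.
#' @export
restore_symmetric <- function(v, P) {
  if (length(v) != n_edges(P))
    stop(sprintf("edge vector has length %d, expected P(P-1)/2 = %d for P = %d",
                 length(v), n_edges(P), P), call. = FALSE)
  m <- matrix(0, P, P)
  m[lower.tri(m)] <- v
  m <- t(m)            # row-major upper triangle
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Construct a cohort table
#'
#' @param X n x p numeric matrix of vectorized edges, one row per subject.
#' @param subject_ids character vector of length n; defaults to `sub_1..n`.
#' @param atlas optional [parcel_atlas()]; its P must satisfy
#'   P(P-1)/2 = ncol(X).
#' @return Object of class `cohort_table` with elements `X`, `subject_ids`,
#'   `atlas`.
#' @export
cohort_table <- function(X, subject_ids = NULL, atlas = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("cohort matrix contains non-finite entries", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- paste0("sub_", seq_len(nrow(X)))
  if (length(subject_ids) != nrow(X))
    stop("subject_ids must have one entry per row of X", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("duplicated subject ids", call. = FALSE)
  if (!is.null(atlas)) {
    P <- n_parcels(atlas)
    if (n_edges(P) != ncol(X))
      stop(sprintf("atlas implies %d edges but cohort has %d columns",
                   n_edges(P), ncol(X)), call. = FALSE)
  }
  const <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    warning(sprintf("%d all-constant edge column(s) in cohort", sum(const)))
  rownames(X) <- subject_ids
  structure(list(X = X, subject_ids = as.character(subject_ids), atlas = atlas),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects x %d edges%s\n",
              nrow(x$X), ncol(x$X),
              if (!is.null(x$atlas)) sprintf(" (P = %d parcels, %d networks)",
                                             n_parcels(x$atlas),
                                             nlevels(x$atlas$network_label))
              else ""))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$X)

#' Read a parcel atlas from a delimited file
#'
#' Expected columns: `parcel_id`, `parcel_name`, `network_label` and
#' optionally `x`, `y`, `z`. Separator is sniffed (comma or tab).
#'
#' @param path file path.
#' @return A [parcel_atlas()].
#' @export
read_atlas <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("parcel_id", "parcel_name", "network_label")
  if (!all(need %in% names(tab)))
    stop("atlas file must have columns parcel_id, parcel_name, network_label",
         call. = FALSE)
  tab <- tab[order(tab$parcel_id), , drop = FALSE]
  if (!identical(as.integer(tab$parcel_id), seq_len(nrow(tab))))
    stop("parcel_id must be 1..P with no gaps", call. = FALSE)
  co <- if (all(c("x", "y", "z") %in% names(tab)))
    as.matrix(tab[, c("x", "y", "z")]) else NULL
  parcel_atlas(tab$parcel_name, tab$network_label, co)
}

#' Load a cohort from delimited files
#'
#' Accepts either one square P x P matrix file per subject, or a single
#' subjects-by-edges table (rows aligned to input order). Subject ids default
#' to file basenames in the per-matrix form.
#'
#' @param paths character vector of per-subject matrix files, or a single
#'   cohort table file.
#' @param atlas a [parcel_atlas()] (optional for the per-matrix form, where
#'   P is taken from the files).
#' @param subject_ids optional explicit subject ids.
#' @param quiet suppress the size message.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(paths, atlas = NULL, subject_ids = NULL, quiet = FALSE) {
  stopifnot(length(paths) >= 1L)
  if (length(paths) == 1L) {
    tab <- as.matrix(read_delim_auto(paths, rownames_col = TRUE))
    if (nrow(tab) == ncol(tab) && isTRUE(all.equal(tab, t(tab), tolerance = 1e-6))) {
      # a single square symmetric file is a one-subject cohort
      v <- vectorize_connectome(tab)
      X <- matrix(v, nrow = 1L)
      ids <- subject_ids %||% sub("\\.[^.]*$", "", basename(paths))
    } else {
      X <- tab
      ids <- subject_ids %||% (rownames(tab) %||% paste0("sub_", seq_len(nrow(tab))))
    }
  } else {
    rows <- lapply(paths, function(p) {
      m <- as.matrix(read_delim_auto(p, header = FALSE))
      vectorize_connectome(m)
    })
    p_each <- lengths(rows)
    if (length(unique(p_each)) != 1L)
      stop("inconsistent matrix dimensions across subject files", call. = FALSE)
    X <- do.call(rbind, rows)
    ids <- subject_ids %||% sub("\\.[^.]*$", "", basename(paths))
  }
  ct <- cohort_table(X, subject_ids = ids, atlas = atlas)
  if (!quiet)
    message(sprintf("loaded cohort: n = %d, p = %d%s", nrow(ct$X), ncol(ct$X),
                    if (!is.null(atlas)) sprintf(", P = %d", n_parcels(atlas)) else ""))
  ct
}

#' Read behavioural scores from a delimited file
#'
#' Expected columns: `subject_id`, `domain`, `score`; missing scores are
#' empty fields or NA. Returns scores for one cognitive domain as a named
#' numeric vector.
#'
#' @param path file path.
#' @param domain which cognitive domain to extract; default the first.
#' @return Named numeric vector (names = subject ids; NA = missing).
#' @export
read_scores <- function(path, domain = NULL) {
  tab <- read_delim_auto(path)
  if (!all(c("subject_id", "score") %in% names(tab)))
    stop("scores file must have columns subject_id, score", call. = FALSE)
  if ("domain" %in% names(tab)) {
    domain <- domain %||% tab$domain[1]
    tab <- tab[tab$domain == domain, , drop = FALSE]
  }
  stats::setNames(as.numeric(tab$score), as.character(tab$subject_id))
}

#' Align a cohort with behavioural scores
#'
#' Keeps the subjects that have a non-missing score, in cohort order
#' (regression uses only scored subjects; feature extraction may still use
#' the full cohort).
#'
#' @param cohort a [cohort_table()].
#' @param scores named numeric vector (names = subject ids) or the output of
#'   [read_scores()]; NA marks a missing score.
#' @return List with `X` (scored subjects x edges, cohort order), `y`
#'   (aligned scores) and `subject_ids`.
#' @export
align_scores <- function(cohort, scores) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(names(scores))) stop("scores must be named by subject id", call. = FALSE)
  y <- scores[cohort$subject_ids]
  keep <- !is.na(y)
  if (sum(keep) < 3L)
    stop(sprintf("need at least 3 scored subjects, found %d", sum(keep)), call. = FALSE)
  list(X = cohort$X[keep, , drop = FALSE],
       y = as.numeric(y[keep]),
       subject_ids = cohort$subject_ids[keep])
}

# Separator-sniffing delimited reader shared by the loaders.
#' @noRd
read_delim_auto <- function(path, header = NA, rownames_col = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  if (is.na(header)) {
    fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (rownames_col && ncol(tab) > 1 &&
      is.character(tab[[1]]) && anyDuplicated(tab[[1]]) == 0) {
    rn <- tab[[1]]
    num <- vapply(tab[-1], is.numeric, logical(1))
    if (all(num)) { tab <- tab[-1]; rownames(tab) <- rn }
  }
  tab
}
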