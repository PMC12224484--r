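#' Edge space of an undirected connectome
#'
#' Fixes the bijection between unordered node pairs \{i < j\} and feature
#' indices 1..Ne with Ne = N(N-1)/2, in row-major order: (1,2), (1,3), ...,
#' (1,N), (2,3), ... All vectorization, masks, and block lookups in the
#' package use this map.
#'
#' @param n_nodes number of nodes N.
#' @return Object of class `edge_space` with `n_nodes`, `n_edges`, and
#'   `pairs` (an Ne x 2 integer matrix of node pairs).
#' @export
edge_space <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 2L)
  pairs <- t(utils::combn(n_nodes, 2L))
  colnames(pairs) <- c("i", "j")
  structure(list(n_nodes = n_nodes, n_edges = nrow(pairs), pairs = pairs),
            class = "edge_space")
}

#' @export
print.edge_space <- function(x, ...) {
  cat(sprintf("Edge space: %d nodes, %d edges (row-major upper triangle)\n",
              x$n_nodes, x$n_edges))
  invisible(x)
}

#' Feature index of a node pair
#'
#' @param space an [edge_space()].
#' @param i,j node indices (vectors, order-free).
#' @return Integer feature indices.
#' @export
edge_index <- function(space, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  stopifnot(all(lo >= 1L), all(hi <= space$n_nodes), all(lo < hi))
  n <- space$n_nodes
  # edges preceding row lo: (lo-1) rows of lengths n-1, n-2, ...
  as.integer((lo - 1) * n - lo * (lo - 1) / 2 + (hi - lo))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param matrix_ an N x N matrix, symmetric within `tol`.
#' @param space the matching [edge_space()].
#' @param tol symmetry tolerance (default 1e-8).
#' @return Numeric vector of length `space$n_edges`.
#' @seealso [reconstruct_edges()] for the inverse map.
#' @export
vectorize_upper <- function(matrix_, space, tol = 1e-8) {
  stopifnot(inherits(space, "edge_space"))
  if (!is.matrix(matrix_) || nrow(matrix_) != space$n_nodes ||
      ncol(matrix_) != space$n_nodes) {
    stop("validation error: matrix dimensions do not match the edge space",
         call. = FALSE)
  }
  if (max(abs(matrix_ - t(matrix_))) > tol) {
    stop("validation error: matrix is not symmetric within tolerance", call. = FALSE)
  }
  matrix_[space$pairs]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' @param values edge vector of length `space$n_edges`.
#' @param space an [edge_space()].
#' @return N x N symmetric matrix with zero diagonal.
#' @export
reconstruct_edges <- function(values, space) {
  stopifnot(inherits(space, "edge_space"), length(values) == space$n_edges)
  m <- matrix(0, space$n_nodes, space$n_nodes)
  m[space$pairs] <- values
  m + t(m)
}

#' Build a feature matrix from a connectome array
#'
#' Vectorizes each subject's matrix into the edge space and keeps the
#' columns selected by `mask` (default: all edges). Column provenance
#' (modality plus original edge index and node pair) is retained so stacked
#' matrices stay interpretable.
#'
#' @param mats nodes x nodes x subjects array (subject ids as the third
#'   dimnames) or a list of per-subject matrices.
#' @param modality modality tag, e.g. `"corr"` or `"FA"`.
#' @param mask integer vector of edge indices to keep (default all).
#' @param tol symmetry tolerance passed to [vectorize_upper()].
#' @return Object of class `feature_matrix`: list with `values`
#'   (subjects x features), `subject_ids`, `modality`, `space`, `mask`,
#'   and `provenance` (data frame: modality, edge, node_i, node_j).
#' @export
connectome_features <- function(mats, modality, mask = NULL, tol = 1e-8) {
  if (is.list(mats)) {
    ids <- names(mats)
    mats <- simplify2array(mats)
    dimnames(mats)[[3]] <- ids
  }
  stopifnot(length(dim(mats)) == 3L)
  ids <- dimnames(mats)[[3]]
  if (is.null(ids)) stop("subject ids missing from the connectome array", call. = FALSE)
  space <- edge_space(dim(mats)[1])
  mask <- sort(as.integer(mask %||% seq_len(space$n_edges)))
  stopifnot(all(mask >= 1L), all(mask <= space$n_edges))
  vals <- t(apply(mats, 3L, vectorize_upper, space = space, tol = tol))
  vals <- vals[, mask, drop = FALSE]
  rownames(vals) <- ids
  prov <- data.frame(modality = rep(modality, length(mask)),
                     edge = mask,
                     node_i = space$pairs[mask, 1L],
                     node_j = space$pairs[mask, 2L],
                     stringsAsFactors = FALSE)
  colnames(vals) <- sprintf("%s_e%d", modality, mask)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("validation error: non-finite values in kept feature columns", call. = FALSE)
  }
  structure(list(values = vals, subject_ids = ids, modality = modality,
                 space = space, mask = mask, provenance = prov),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$provenance$modality), collapse = " + ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Group proportional threshold
#'
#' Keeps an edge iff it is nonzero (strictly) in at least
#' `ceiling(fraction * n_subjects)` subjects; the resulting mask applies
#' identically to every subject. Intended for sparse structural channels;
#' dense functional matrices are left unthresholded in the pipeline.
#'
#' @param mats nodes x nodes x subjects array or list of matrices.
#' @param fraction required presence fraction in (0, 1] (default 2/3).
#' @return Integer vector of kept edge indices (attribute `n_total` holds
#'   the edge-space size).
#' @export
proportional_threshold <- function(mats, fraction = 2 / 3) {
  if (is.list(mats)) mats <- simplify2array(mats)
  if (length(dim(mats)) != 3L || dim(mats)[3] < 1L) {
    stop("validation error: need at least one subject matrix", call. = FALSE)
  }
  stopifnot(fraction > 0, fraction <= 1)
  space <- edge_space(dim(mats)[1])
  n_subj <- dim(mats)[3]
  pres <- apply(mats, 3L, function(m) abs(m[space$pairs]) > 0)
  if (is.null(dim(pres))) pres <- matrix(pres, ncol = n_subj)
  counts <- rowSums(pres)
  keep <- which(counts >= ceiling(fraction * n_subj))
  structure(as.integer(keep), n_total = space$n_edges)
}

#' Stack two modalities into one feature matrix
#'
#' Concatenates the structural kept-features after the functional ones,
#' subject-wise; provenance of every column is preserved.
#'
#' @param functional,structural `feature_matrix` objects over identical
#'   subject-id sequences.
#' @return A combined `feature_matrix` (its `modality` is
#'   `"functional+structural"` tags joined with `+`).
#' @export
stack_modalities <- function(functional, structural) {
  stopifnot(inherits(functional, "feature_matrix"),
            inherits(structural, "feature_matrix"))
  if (!identical(functional$subject_ids, structural$subject_ids)) {
    bad <- union(setdiff(functional$subject_ids, structural$subject_ids),
                 setdiff(structural$subject_ids, functional$subject_ids))
    stop("alignment error: subject ids differ between modalities: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         if (!length(bad)) " (same ids, different order)" else "",
         call. = FALSE)
  }
  vals <- cbind(functional$values, structural$values)
  structure(list(values = vals,
                 subject_ids = functional$subject_ids,
                 modality = paste(functional$modality, structural$modality, sep = "+"),
                 space = functional$space,
                 mask = functional$mask,
                 structural_space = structural$space,
                 structural_mask = structural$mask,
                 provenance = rbind(functional$provenance, structural$provenance)),
            class = "feature_matrix")
}

#' Fit and apply training-set z-normalization
#'
#' `fit_znorm()` estimates per-feature mean and standard deviation
#' (denominator n-1) on a training subject subset; `apply_znorm()`
#' standardizes any feature matrix with those statistics. Zero-variance
#' training columns are mapped to all-zeros (with a warning at fit time) so
#' dead features get exactly zero ridge coefficients. Fitting and applying
#' are separate calls precisely so that validation/test rows can never leak
#' into the statistics.
#'
#' @param x a `feature_matrix` or plain numeric matrix.
#' @param rows subject ids (or row indices) of the training subset; default
#'   all rows.
#' @return `fit_znorm()`: object of class `znorm_stats` with `mean`, `sd`,
#'   and `constant` (logical). `apply_znorm()`: matrix of standardized
#'   values with the input's rows.
#' @export
fit_znorm <- function(x, rows = NULL) {
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (!is.null(rows)) {
    if (is.character(rows)) rows <- match(rows, rownames(vals))
    vals <- vals[rows, , drop = FALSE]
  }
  if (nrow(vals) < 2L) {
    stop("validation error: z-normalization needs at least two training subjects",
         call. = FALSE)
  }
  mu <- colMeans(vals)
  sd_ <- apply(vals, 2L, stats::sd)
  constant <- sd_ == 0 | !is.finite(sd_)
  if (any(constant)) {
    warning(sum(constant), " zero-variance training column(s) mapped to zeros")
    sd_[constant] <- 1
  }
  structure(list(mean = mu, sd = sd_, constant = constant), class = "znorm_stats")
}

#' @rdname fit_znorm
#' @param stats_ a `znorm_stats` object from `fit_znorm()`.
#' @export
apply_znorm <- function(x, stats_) {
  stopifnot(inherits(stats_, "znorm_stats"))
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  stopifnot(ncol(vals) == length(stats_$mean))
  out <- sweep(sweep(vals, 2L, stats_$mean, "-"), 2L, stats_$sd, "/")
  if (any(stats_$constant)) out[, stats_$constant] <- 0
  out
}
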