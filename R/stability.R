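#' Six-way node partition of the functional connectome
#'
#' @param sizes subnetwork sizes (default the package's 55-node split).
#' @param labels subnetwork labels.
#' @return Object of class `node_partition`: per-node labels (factor),
#'   `sizes`, `n_nodes`.
#' @export
node_partition <- function(sizes = c(10L, 9L, 12L, 8L, 8L, 8L),
                           labels = c("SMN", "VN", "EC_AN", "CON", "DMN", "eDMN")) {
  stopifnot(length(sizes) == length(labels), all(sizes >= 1))
  node_labels <- factor(rep(labels, sizes), levels = labels)
  structure(list(labels = node_labels, sizes = stats::setNames(as.integer(sizes), labels),
                 n_nodes = sum(sizes)),
            class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat("Node partition:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Partition implied by a cohort configuration
#'
#' @param config a [cohort_config()].
#' @export
config_partition <- function(config) {
  node_partition(config$subnetwork_sizes, config$subnetwork_labels)
}

# Coefficient matrix (features x models) from whatever the caller has.
coef_matrix <- function(models) {
  if (inherits(models, "nested_ridge")) return(coef(models, type = "matrix"))
  if (is.list(models)) {
    vecs <- lapply(models, function(m) {
      if (inherits(m, "logistic_ridge")) m$coefficients else as.numeric(m)
    })
    if (length(unique(lengths(vecs))) != 1L) {
      stop("validation error: models have differing feature counts", call. = FALSE)
    }
    return(do.call(cbind, vecs))
  }
  as.matrix(models)
}

#' Select robustly important features across fold models
#'
#' A feature is important iff, in every one of the fold models, (a) its
#' coefficient magnitude ranks within the top half (rank at most
#' `floor(p/2)` of the `p` features, descending by `|beta|`, ties broken by
#' ascending feature index) and (b) its coefficient carries the same
#' nonzero sign. Both criteria must hold in all models simultaneously.
#'
#' @param models a `nested_ridge` fit, a list of `logistic_ridge` models or
#'   coefficient vectors, or a features x models coefficient matrix.
#' @return Object of class `important_features`: integer `indices`, their
#'   `signs` (+1/-1), the count `K`, feature `names`, and (when available
#'   from a `nested_ridge`) the phenotype/modality/threshold metadata and
#'   edge provenance.
#' @export
important_features <- function(models) {
  mat <- coef_matrix(models)
  p <- nrow(mat)
  if (any(!is.finite(mat))) {
    stop("validation error: non-finite coefficients", call. = FALSE)
  }
  cutoff <- floor(p / 2)
  in_top <- matrix(FALSE, p, ncol(mat))
  for (k in seq_len(ncol(mat))) {
    ord <- order(-abs(mat[, k]), seq_len(p))
    rk <- integer(p)
    rk[ord] <- seq_len(p)
    in_top[, k] <- rk <= cutoff
  }
  signs <- sign(mat)
  consistent_sign <- rowSums(signs == 1) == ncol(mat) |
    rowSums(signs == -1) == ncol(mat)
  keep <- which(rowSums(in_top) == ncol(mat) & consistent_sign)
  meta <- if (inherits(models, "nested_ridge")) {
    list(phenotype = models$phenotype, modality = models$modality,
         ctq_threshold = models$ctq_threshold,
         provenance = if (!is.null(models$provenance))
           models$provenance[keep, , drop = FALSE] else NULL)
  } else {
    list(phenotype = NA_character_, modality = NA_character_,
         ctq_threshold = NA_real_, provenance = NULL)
  }
  structure(list(indices = keep,
                 signs = as.integer(signs[keep, 1]),
                 K = length(keep),
                 names = rownames(mat)[keep],
                 n_features = p,
                 phenotype = meta$phenotype,
                 modality = meta$modality,
                 ctq_threshold = meta$ctq_threshold,
                 provenance = meta$provenance),
            class = "important_features")
}

#' @export
print.important_features <- function(x, ...) {
  cat(sprintf("Important features: K = %d of %d (%d positive, %d negative)\n",
              x$K, x$n_features, sum(x$signs > 0), sum(x$signs < 0)))
  invisible(x)
}

#' Jaccard index of two feature sets
#'
#' `|a intersect b| / |a union b|`; two empty sets are treated as identical
#' (index 1).
#'
#' @param a,b `important_features` objects or plain index/name vectors over
#'   the same feature space.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  ai <- if (inherits(a, "important_features")) a$indices else a
  bi <- if (inherits(b, "important_features")) b$indices else b
  u <- length(union(ai, bi))
  if (u == 0L) return(1)
  length(intersect(ai, bi)) / u
}

#' Mean coefficient vector across fold models
#'
#' @param models as in [important_features()].
#' @return Per-feature arithmetic mean coefficient.
#' @export
mean_coefficients <- function(models) {
  rowMeans(coef_matrix(models))
}

#' Normalized aggregated block coefficients
#'
#' Aggregates mean coefficients of the important edges within each
#' subnetwork block and normalizes by the total absolute mean-coefficient
#' mass over all edges:
#' \deqn{\beta^{norm}_{ij} = \sum_{e \in block(i,j) \cap important}
#'   \bar\beta_e \; / \; \sum_{e} |\bar\beta_e|.}
#' The sign says whether the block is positively or negatively predictive
#' of case status; magnitudes are small fractions of the model's total
#' coefficient mass. (The aggregation rule is this package's formulation
#' of a block-level predictive-direction summary.)
#'
#' @param beta_mean per-edge mean coefficients over the full edge space of
#'   `space` (functional edges only for stacked models).
#' @param important an `important_features` over the same edge indexing.
#' @param partition a [node_partition()].
#' @param space the functional [edge_space()].
#' @return Symmetric 6 x 6 matrix of class `matrix` (upper triangle
#'   canonical) with subnetwork dimnames.
#' @export
block_coefficients <- function(beta_mean, important, partition, space) {
  stopifnot(inherits(partition, "node_partition"), inherits(space, "edge_space"),
            length(beta_mean) == space$n_edges,
            partition$n_nodes == space$n_nodes)
  idx <- if (inherits(important, "important_features")) important$indices else important
  g <- length(partition$sizes)
  out <- matrix(0, g, g, dimnames = list(names(partition$sizes),
                                         names(partition$sizes)))
  denom <- sum(abs(beta_mean))
  if (denom == 0) {
    warning("all mean coefficients are zero; block coefficients set to zero")
    return(out)
  }
  grp <- as.integer(partition$labels)
  for (e in idx) {
    gi <- grp[space$pairs[e, 1L]]
    gj <- grp[space$pairs[e, 2L]]
    lo <- min(gi, gj); hi <- max(gi, gj)
    out[lo, hi] <- out[lo, hi] + beta_mean[e]
  }
  out <- out / denom
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Export important edges as an annotated edge list
#'
#' One row per important edge with its nodes, subnetworks, coefficient
#' sign, and mean coefficient; suitable input for circular-plot tools.
#'
#' @param important an `important_features` over `space`.
#' @param partition a [node_partition()].
#' @param space the [edge_space()].
#' @param beta_mean optional per-edge mean coefficients.
#' @return A data frame.
#' @export
important_edge_list <- function(important, partition, space, beta_mean = NULL) {
  stopifnot(inherits(important, "important_features"))
  idx <- important$indices
  gi <- as.character(partition$labels[space$pairs[idx, 1L]])
  gj <- as.character(partition$labels[space$pairs[idx, 2L]])
  data.frame(node_i = space$pairs[idx, 1L],
             node_j = space$pairs[idx, 2L],
             subnetwork_i = gi,
             subnetwork_j = gj,
             sign = important$signs,
             beta_mean = if (is.null(beta_mean)) NA_real_ else beta_mean[idx],
             stringsAsFactors = FALSE)
}
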