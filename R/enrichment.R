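#' Block capacity matrix of a node partition
#'
#' Number of possible edges within and between subnetworks:
#' \eqn{S_{ij} = n_i n_j} for \eqn{i \neq j} and \eqn{n_i(n_i-1)/2} on the
#' diagonal. The upper triangle (diagonal included) sums to
#' \eqn{N_e = N(N-1)/2}.
#'
#' @param partition a [node_partition()].
#' @return Symmetric integer matrix with subnetwork dimnames.
#' @export
block_capacity <- function(partition) {
  stopifnot(inherits(partition, "node_partition"))
  n <- partition$sizes
  s <- outer(n, n)
  diag(s) <- n * (n - 1) / 2
  s
}

#' Observed important-edge counts per block
#'
#' Tallies each important edge into the unordered subnetwork pair of its
#' two end nodes; the upper triangle sums to K.
#'
#' @param important an `important_features` (or integer edge indices).
#' @param partition a [node_partition()].
#' @param space the [edge_space()] the indices refer to.
#' @return Symmetric count matrix.
#' @export
observed_block_counts <- function(important, partition, space) {
  stopifnot(inherits(partition, "node_partition"), inherits(space, "edge_space"),
            partition$n_nodes == space$n_nodes)
  idx <- if (inherits(important, "important_features")) important$indices else
    as.integer(important)
  if (length(idx) && (min(idx) < 1L || max(idx) > space$n_edges)) {
    stop("validation error: edge index outside the edge space", call. = FALSE)
  }
  g <- length(partition$sizes)
  grp <- as.integer(partition$labels)
  o <- matrix(0L, g, g, dimnames = list(names(partition$sizes),
                                        names(partition$sizes)))
  for (e in idx) {
    gi <- grp[space$pairs[e, 1L]]
    gj <- grp[space$pairs[e, 2L]]
    lo <- min(gi, gj); hi <- max(gi, gj)
    o[lo, hi] <- o[lo, hi] + 1L
  }
  o[lower.tri(o)] <- t(o)[lower.tri(o)]
  o
}

#' Hypergeometric block p-values
#'
#' Tests, for every subnetwork block, whether it holds more or fewer
#' important edges than expected when K important edges are drawn without
#' replacement from the Ne edges of the connectome. With X distributed
#' hypergeometric (population `Ne`, successes `S_ij`, draws `K`): if
#' \eqn{O_{ij} \le K S_{ij} / N_e} the lower-tail probability
#' \eqn{P[X \le O_{ij}]} is reported (direction `"fewer"`), otherwise the
#' upper tail \eqn{P[X \ge O_{ij}]} (direction `"more"`). At the expected
#' value exactly, the lower tail is used.
#'
#' @param observed symmetric observed count matrix (from
#'   [observed_block_counts()]).
#' @param capacity symmetric capacity matrix (from [block_capacity()]).
#' @param n_important K, total number of important edges.
#' @param n_edges Ne, total number of edges.
#' @return List with matrices `p` (in (0, 1]) and `tail`
#'   (`"fewer"`/`"more"`).
#' @export
hypergeom_block_pvalues <- function(observed, capacity, n_important, n_edges) {
  if (n_important > n_edges || any(capacity > n_edges)) {
    stop("validation error: K and S must not exceed Ne", call. = FALSE)
  }
  if (any(observed > pmin(capacity, n_important))) {
    stop("validation error: observed counts exceed min(S, K)", call. = FALSE)
  }
  expected <- n_important * capacity / n_edges
  lower <- observed <= expected
  p <- matrix(NA_real_, nrow(observed), ncol(observed), dimnames = dimnames(observed))
  p[lower] <- stats::phyper(observed[lower], capacity[lower],
                            n_edges - capacity[lower], n_important)
  p[!lower] <- stats::phyper(observed[!lower] - 1L, capacity[!lower],
                             n_edges - capacity[!lower], n_important,
                             lower.tail = FALSE)
  tail <- matrix(ifelse(lower, "fewer", "more"), nrow(observed),
                 dimnames = dimnames(observed))
  list(p = p, tail = tail)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (wrapper
#' around [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Subnetwork enrichment of important edges
#'
#' The full block analysis for one fitted model: observed counts, block
#' capacities, two-sided-by-direction hypergeometric p-values, and
#' Benjamini-Hochberg q-values. The BH family is the set of testable
#' blocks of this one model (the 21 upper-triangle cells for six
#' subnetworks; blocks with zero capacity are skipped and excluded from
#' the family). Optionally attaches [block_coefficients()].
#'
#' @param important an `important_features`.
#' @param partition a [node_partition()].
#' @param space the functional [edge_space()].
#' @param beta_mean optional per-edge mean coefficients for the
#'   `beta_norm` summary.
#' @return Object of class `subnetwork_enrichment`: matrices `observed`,
#'   `capacity`, `p`, `q`, `tail`, `beta_norm` (or `NULL`), and scalars
#'   `K`, `n_edges`.
#' @export
subnetwork_enrichment <- function(important, partition, space, beta_mean = NULL) {
  o <- observed_block_counts(important, partition, space)
  s <- block_capacity(partition)
  k <- if (inherits(important, "important_features")) important$K else
    length(important)
  ne <- space$n_edges
  ht <- hypergeom_block_pvalues(o, s, k, ne)
  ut <- upper.tri(s, diag = TRUE)
  family <- which(ut & s > 0)
  q <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  q[family] <- bh_adjust(ht$p[family])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  bn <- if (!is.null(beta_mean)) {
    block_coefficients(beta_mean, important, partition, space)
  }
  structure(list(observed = o, capacity = s, p = ht$p, q = q, tail = ht$tail,
                 beta_norm = bn, K = k, n_edges = ne,
                 phenotype = if (inherits(important, "important_features"))
                   important$phenotype else NA_character_),
            class = "subnetwork_enrichment")
}

#' @export
print.subnetwork_enrichment <- function(x, digits = 4, ...) {
  cat(sprintf("Subnetwork enrichment: K = %d important of %d edges\n",
              x$K, x$n_edges))
  df <- as.data.frame(x)
  df$p <- signif(df$p, digits)
  df$q <- signif(df$q, digits)
  if (!is.null(df$beta_norm)) df$beta_norm <- signif(df$beta_norm, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy long-format enrichment table
#'
#' @param x a `subnetwork_enrichment`.
#' @param ... unused.
#' @return Data frame with one row per testable block.
#' @export
as.data.frame.subnetwork_enrichment <- function(x, ...) {
  labs <- rownames(x$capacity)
  g <- length(labs)
  rows <- which(upper.tri(x$capacity, diag = TRUE) & x$capacity > 0,
                arr.ind = TRUE)
  rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
  out <- data.frame(block_i = labs[rows[, 1L]],
                    block_j = labs[rows[, 2L]],
                    observed = x$observed[rows],
                    capacity = x$capacity[rows],
                    p = x$p[rows],
                    q = x$q[rows],
                    tail = x$tail[rows],
                    stringsAsFactors = FALSE)
  if (!is.null(x$beta_norm)) out$beta_norm <- x$beta_norm[rows]
  out
}
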