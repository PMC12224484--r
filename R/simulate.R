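#' Base functional block covariance
#'
#' Exchangeable-block correlation matrix over the functional nodes: unit
#' diagonal, `within_cor` inside each subnetwork, `between_cor` across
#' subnetworks. This is the control-group population covariance from which
#' subject time series are drawn.
#'
#' @param config a [cohort_config()].
#' @return A `functional_nodes` x `functional_nodes` correlation matrix.
#' @export
base_block_covariance <- function(config) {
  n <- config$functional_nodes
  grp <- rep(seq_along(config$subnetwork_sizes), config$subnetwork_sizes)
  sigma <- matrix(config$between_cor, n, n)
  same <- outer(grp, grp, "==")
  sigma[same] <- config$within_cor
  diag(sigma) <- 1
  sigma
}

# Case covariance: shift target-block correlations on the Fisher-z scale by
# delta * (1 + ctq_slope * ctq), mapped back through tanh.
effect_covariance <- function(config, shift) {
  sigma <- base_block_covariance(config)
  if (shift != 0) {
    grp <- rep(seq_along(config$subnetwork_sizes), config$subnetwork_sizes)
    for (blk in config$target_blocks) {
      rows <- which(grp == blk[1]); cols <- which(grp == blk[2])
      idx <- expand.grid(i = rows, j = cols)
      idx <- idx[idx$i != idx$j, , drop = FALSE]
      z <- atanh(sigma[cbind(idx$i, idx$j)]) + shift
      sigma[cbind(idx$i, idx$j)] <- tanh(z)
      sigma[cbind(idx$j, idx$i)] <- tanh(z)
    }
  }
  sigma
}

# Cholesky with the module's error contract.
chol_or_stop <- function(sigma) {
  tryCatch(chol(sigma), error = function(e) {
    stop("generation error: subject covariance is not positive definite ",
         "(check within_cor/between_cor/delta)", call. = FALSE)
  })
}

#' Simulate one subject's functional connectomes
#'
#' Draws `ts_length` multivariate-normal time points from the subject's
#' population covariance (the base block covariance, with target-block
#' correlations shifted by `delta * (1 + ctq_slope * ctq)` on the Fisher-z
#' scale when the subject is a case under `effect_phenotype`), then returns
#' the Fisher-z full correlation matrix and the Fisher-z partial correlation
#' matrix computed from the Tikhonov-regularized inverse sample correlation
#' (`pcor_rho`).
#'
#' @param subject one-row data frame with phenotype flags and `ctq`.
#' @param config a [cohort_config()].
#' @param seed optional integer; when given, the draw is made under this
#'   seed without disturbing the caller's RNG stream.
#' @return List with symmetric zero-diagonal matrices `corr` and `pcorr`.
#' @export
simulate_functional <- function(subject, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), nrow(subject) == 1L)
  if (is.null(subject[[config$effect_phenotype]])) {
    stop("subject has no phenotype flags; run assign_phenotypes() first",
         call. = FALSE)
  }
  is_case <- isTRUE(subject[[config$effect_phenotype]])
  shift <- if (is_case) config$delta * (1 + config$ctq_slope * subject$ctq) else 0
  cf <- chol_or_stop(effect_covariance(config, shift))
  with_seed(seed, {
    ts <- matrix(stats::rnorm(config$ts_length * config$functional_nodes),
                 config$ts_length) %*% cf
    r <- stats::cor(ts)
    r <- (r + t(r)) / 2  # enforce exact symmetry against float drift
    full <- r; diag(full) <- 0; full <- atanh(full)
    theta <- solve(r + diag(config$pcor_rho, config$functional_nodes))
    d <- sqrt(diag(theta))
    pc <- -theta / outer(d, d)
    pc <- (pc + t(pc)) / 2
    diag(pc) <- 0  # keep the -1 self-partial-correlation out of atanh
    pz <- atanh(pc)
    list(corr = full, pcorr = pz)
  })
}

#' Simulate functional connectomes for (a subset of) a cohort
#'
#' Per-subject sub-seeds are derived from the configuration seed and the
#' subject's position in the full cohort, so matrices are bit-identical
#' whether simulated for everyone or only for, say, the matched subjects.
#'
#' @param cohort a `conn_cohort`.
#' @param ids subject ids to simulate (default: all).
#' @return List of two arrays (`corr`, `pcorr`) of dimension
#'   nodes x nodes x subjects, subject ids on the third dimension.
#' @export
simulate_functional_cohort <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "conn_cohort"))
  subjects <- cohort$subjects
  ids <- ids %||% subjects$id
  pos <- match(ids, subjects$id)
  if (anyNA(pos)) stop("unknown subject ids: ", paste(ids[is.na(pos)], collapse = ", "))
  n <- cohort$config$functional_nodes
  corr <- array(NA_real_, c(n, n, length(ids)), dimnames = list(NULL, NULL, ids))
  pcorr <- corr
  # cache Cholesky factors across subjects sharing an effect shift
  cache <- new.env(parent = emptyenv())
  cfg <- cohort$config
  for (k in seq_along(ids)) {
    subj <- subjects[pos[k], , drop = FALSE]
    is_case <- isTRUE(subj[[cfg$effect_phenotype]])
    shift <- if (is_case) cfg$delta * (1 + cfg$ctq_slope * subj$ctq) else 0
    key <- sprintf("%.12g", shift)
    if (is.null(cache[[key]])) cache[[key]] <- chol_or_stop(effect_covariance(cfg, shift))
    cf <- cache[[key]]
    mats <- with_seed(derive_seed(cfg$seed, 1000000 + pos[k]), {
      ts <- matrix(stats::rnorm(cfg$ts_length * n), cfg$ts_length) %*% cf
      r <- stats::cor(ts)
      r <- (r + t(r)) / 2
      full <- r; diag(full) <- 0; full <- atanh(full)
      theta <- solve(r + diag(cfg$pcor_rho, n))
      d <- sqrt(diag(theta))
      pc <- -theta / outer(d, d)
      pc <- (pc + t(pc)) / 2
      diag(pc) <- 0
      pz <- atanh(pc)
      list(full, pz)
    })
    corr[, , k] <- mats[[1]]
    pcorr[, , k] <- mats[[2]]
  }
  list(corr = corr, pcorr = pcorr)
}

# Shared structural base topology and edge log-weights, derived from the
# configuration seed so every subject sees the same base network.
structural_base <- function(config) {
  with_seed(derive_seed(config$seed, 777), {
    n <- config$structural_nodes
    pres <- matrix(FALSE, n, n)
    ut <- upper.tri(pres)
    pres[ut] <- stats::runif(sum(ut)) < config$edge_presence
    pres <- pres | t(pres)
    mu <- matrix(0, n, n)
    mu[ut] <- stats::rnorm(sum(ut), 0, 0.6)
    mu <- mu + t(mu)
    list(presence = pres, log_weight = mu)
  })
}

# Fixed per-channel log-scale offsets (arbitrary units; the classifier only
# sees relative edge weights within a channel).
channel_offsets <- function(channels) {
  defaults <- c(SC = 2, FA = -0.5, MD = -1, ICVF = -0.3, ISOVF = -1.2, OD = -0.8)
  out <- defaults[channels]
  out[is.na(out)] <- 0
  names(out) <- channels
  out
}

#' Simulate one subject's structural connectomes
#'
#' All subjects share one base topology (edge presence probability
#' `edge_presence`); each present edge is observed in a given subject with
#' probability `reliability`, absent edges are exact zeros. Observed edge
#' weights are log-normal per channel with an edge-level component shared
#' across channels (channel-correlated noise). For case subjects (under
#' `effect_phenotype`) the log-weights of edges among
#' `structural_target_nodes` are shifted by `delta_s`.
#'
#' @param subject one-row data frame with phenotype flags.
#' @param config a [cohort_config()].
#' @param base optional precomputed [structural_base()] result.
#' @param seed optional integer seed for the subject draw.
#' @return Named list of symmetric non-negative zero-diagonal matrices, one
#'   per structural channel.
#' @export
simulate_structural <- function(subject, config, base = NULL, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), nrow(subject) == 1L)
  if (config$reliability <= 0 || config$reliability > 1) {
    stop("configuration error: `reliability` must lie in (0, 1]", call. = FALSE)
  }
  base <- base %||% structural_base(config)
  is_case <- isTRUE(subject[[config$effect_phenotype]])
  n <- config$structural_nodes
  channels <- config$structural_channels
  offs <- channel_offsets(channels)
  tgt <- matrix(FALSE, n, n)
  tgt[config$structural_target_nodes, config$structural_target_nodes] <- TRUE
  with_seed(seed, {
    ut <- upper.tri(base$presence)
    present <- base$presence[ut]
    keep <- present & (stats::runif(length(present)) < config$reliability)
    shared <- stats::rnorm(length(present), 0, 0.4)
    out <- vector("list", length(channels))
    names(out) <- channels
    for (ch in channels) {
      lw <- base$log_weight[ut] + offs[[ch]] + shared +
        stats::rnorm(length(present), 0, 0.25)
      if (is_case && config$delta_s != 0) lw <- lw + config$delta_s * tgt[ut]
      w <- ifelse(keep, exp(lw), 0)
      m <- matrix(0, n, n)
      m[ut] <- w
      out[[ch]] <- m + t(m)
    }
    out
  })
}

#' Simulate structural connectomes for (a subset of) a cohort
#'
#' @param cohort a `conn_cohort`.
#' @param ids subject ids to simulate (default: all).
#' @param channels structural channels to simulate (default: all configured).
#' @return Named list of nodes x nodes x subjects arrays, one per channel.
#' @export
simulate_structural_cohort <- function(cohort, ids = NULL, channels = NULL) {
  stopifnot(inherits(cohort, "conn_cohort"))
  cfg <- cohort$config
  subjects <- cohort$subjects
  ids <- ids %||% subjects$id
  pos <- match(ids, subjects$id)
  if (anyNA(pos)) stop("unknown subject ids: ", paste(ids[is.na(pos)], collapse = ", "))
  channels <- channels %||% cfg$structural_channels
  base <- structural_base(cfg)
  n <- cfg$structural_nodes
  out <- lapply(channels, function(ch)
    array(NA_real_, c(n, n, length(ids)), dimnames = list(NULL, NULL, ids)))
  names(out) <- channels
  for (k in seq_along(ids)) {
    mats <- simulate_structural(subjects[pos[k], , drop = FALSE], cfg, base = base,
                                seed = derive_seed(cfg$seed, 2000000 + pos[k]))
    for (ch in channels) out[[ch]][, , k] <- mats[[ch]]
  }
  out
}
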