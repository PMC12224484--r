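#' Define an experiment grid
#'
#' The cross of phenotypes, connectome modalities, CTQ thresholds, and an
#' optional sex stratum. Functional modalities are `"corr"` and `"pcorr"`;
#' structural channels by their configured names (e.g. `"FA"`); combined
#' modalities as `"corr+FA"` (structural features stacked after the
#' functional ones).
#'
#' @param phenotypes subset of the six phenotype flags.
#' @param modalities character vector of modality tags.
#' @param ctq_thresholds numeric vector; use `NA` for "no threshold".
#' @param sex `"all"`, `"female"`, or `"male"`.
#' @return Data frame with one row per grid cell.
#' @export
experiment_grid <- function(phenotypes = "current",
                            modalities = "corr",
                            ctq_thresholds = NA_real_,
                            sex = "all") {
  stopifnot(length(phenotypes) > 0, length(modalities) > 0,
            length(ctq_thresholds) > 0, sex %in% c("all", "female", "male"))
  grid <- expand.grid(phenotype = phenotypes, modality = modalities,
                      ctq = as.numeric(ctq_thresholds), sex = sex,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$phenotype, grid$modality, grid$ctq, na.last = FALSE), ,
       drop = FALSE]
}

# Parse "corr", "FA" or "corr+FA" against a configuration.
parse_modality <- function(modality, config) {
  parts <- strsplit(modality, "+", fixed = TRUE)[[1]]
  func <- intersect(parts, c("corr", "pcorr"))
  struct <- intersect(parts, config$structural_channels)
  if (length(func) + length(struct) != length(parts) || length(func) > 1L ||
      length(struct) > 1L) {
    stop("unknown modality: ", modality, " (expected corr/pcorr, a structural ",
         "channel, or functional+structural)", call. = FALSE)
  }
  list(functional = if (length(func)) func else NULL,
       structural = if (length(struct)) struct else NULL)
}

# Build the feature matrix for one modality over a set of subject ids,
# using caches of simulated arrays keyed by modality.
cell_features <- function(cohort, modality, ids, cache, fraction = 2 / 3) {
  cfg <- cohort$config
  parts <- parse_modality(modality, cfg)
  get_functional <- function(tag) {
    key <- paste0("f_", tag)
    have <- cache[[key]]
    need <- if (is.null(have)) ids else setdiff(ids, dimnames(have)[[3]])
    if (length(need)) {
      sim <- simulate_functional_cohort(cohort, need)[[tag]]
      cache[[key]] <- if (is.null(have)) sim else {
        arr <- array(NA_real_, dim(have) + c(0, 0, length(need)),
                     dimnames = list(NULL, NULL, c(dimnames(have)[[3]], need)))
        arr[, , seq_len(dim(have)[3])] <- have
        arr[, , dim(have)[3] + seq_along(need)] <- sim
        arr
      }
    }
    cache[[key]][, , ids, drop = FALSE]
  }
  get_structural <- function(ch) {
    key <- paste0("s_", ch)
    have <- cache[[key]]
    need <- if (is.null(have)) ids else setdiff(ids, dimnames(have)[[3]])
    if (length(need)) {
      sim <- simulate_structural_cohort(cohort, need, channels = ch)[[ch]]
      cache[[key]] <- if (is.null(have)) sim else {
        arr <- array(NA_real_, dim(have) + c(0, 0, length(need)),
                     dimnames = list(NULL, NULL, c(dimnames(have)[[3]], need)))
        arr[, , seq_len(dim(have)[3])] <- have
        arr[, , dim(have)[3] + seq_along(need)] <- sim
        arr
      }
    }
    cache[[key]][, , ids, drop = FALSE]
  }
  fm_f <- if (!is.null(parts$functional)) {
    connectome_features(get_functional(parts$functional), parts$functional)
  }
  fm_s <- if (!is.null(parts$structural)) {
    arr <- get_structural(parts$structural)
    mask <- proportional_threshold(arr, fraction)
    connectome_features(arr, parts$structural, mask = mask)
  }
  if (!is.null(fm_f) && !is.null(fm_s)) {
    stack_modalities(fm_f, fm_s)
  } else {
    fm_f %||% fm_s
  }
}

# Functional sub-part of an importance analysis on possibly stacked features.
functional_part <- function(fit, important, beta_mean) {
  if (is.null(fit$provenance)) return(NULL)
  fun_cols <- which(fit$provenance$modality %in% c("corr", "pcorr"))
  if (!length(fun_cols)) return(NULL)
  space <- edge_space(max(fit$provenance$node_j[fun_cols]))
  # functional features are never masked, so column index == edge index
  list(space = space,
       important_edges = intersect(important$indices, fun_cols),
       beta_mean = beta_mean[fun_cols])
}

#' Run the full experiment grid on a cohort
#'
#' For every grid cell: CTQ-filter the cases, match controls, build the
#' cell's feature matrix (simulating connectomes only for matched
#' subjects), run the nested cross-validated ridge classifier, select
#' stable important features, and (for cells with a functional component)
#' compute the subnetwork enrichment. Cell failures are caught and
#' reported per cell without aborting the grid. When `out_dir` is given,
#' each completed cell is checkpointed as a JSON artifact keyed by
#' (configuration seed, cell, run seed) and skipped on re-runs.
#'
#' @param cohort a `conn_cohort`.
#' @param grid an [experiment_grid()].
#' @param lambda penalty grid.
#' @param n_outer,n_inner fold counts.
#' @param seed integer; every cell derives its own fold-plan seed from it.
#' @param n_pairs optional cap on pairs per cell.
#' @param fraction proportional-threshold fraction for structural channels.
#' @param out_dir optional artifact/checkpoint directory.
#' @param keep_fits keep the full `nested_ridge` objects per cell (memory
#'   permitting); summaries and important-feature sets are always kept.
#' @return Object of class `experiment_report` with `cells` (one summary
#'   row per cell) and `details` (per-cell list: accuracies, chosen
#'   lambdas, `important`, `enrichment`, optionally `fit`).
#' @export
run_experiment <- function(cohort, grid = experiment_grid(),
                           lambda = lambda_grid(), n_outer = 6L, n_inner = 5L,
                           seed = 1L, n_pairs = NULL, fraction = 2 / 3,
                           out_dir = NULL, keep_fits = FALSE) {
  stopifnot(inherits(cohort, "conn_cohort"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cache <- new.env(parent = emptyenv())
  cells <- vector("list", nrow(grid))
  details <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    tau <- if (is.na(cell$ctq)) NULL else cell$ctq
    cell_key <- sprintf("cohort%d_seed%d_%s_%s_ctq%s_%s",
                        cohort$config$seed, seed, cell$phenotype, cell$modality,
                        ifelse(is.na(cell$ctq), "none", format(cell$ctq)),
                        cell$sex)
    cell_key <- gsub("[^A-Za-z0-9_.-]", "-", cell_key)
    ckpt <- if (!is.null(out_dir)) file.path(out_dir, paste0(cell_key, ".json"))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      saved <- jsonlite::read_json(ckpt, simplifyVector = TRUE)
      cells[[i]] <- as.data.frame(saved$summary, stringsAsFactors = FALSE)
      details[[i]] <- list(accuracy = saved$accuracy, lambda = saved$lambda,
                           important_indices = saved$important_indices,
                           from_checkpoint = TRUE)
      next
    }
    res <- tryCatch({
      sample <- match_cases(cohort, cell$phenotype, ctq_threshold = tau,
                            sex = cell$sex, n_pairs = n_pairs)
      fm <- cell_features(cohort, cell$modality, matched_ids(sample), cache,
                          fraction = fraction)
      fit <- nested_ridge(fm, sample, lambda = lambda, n_outer = n_outer,
                          n_inner = n_inner, seed = derive_seed(seed, i))
      imp <- important_features(fit)
      bm <- mean_coefficients(fit)
      fun <- functional_part(fit, imp, bm)
      enr <- if (!is.null(fun)) {
        subnetwork_enrichment(
          structure(list(indices = fun$important_edges,
                         K = length(fun$important_edges),
                         signs = imp$signs[match(fun$important_edges, imp$indices)],
                         phenotype = cell$phenotype),
                    class = "important_features"),
          config_partition(cohort$config), fun$space, beta_mean = fun$beta_mean)
      }
      summary_row <- data.frame(
        phenotype = cell$phenotype, modality = cell$modality,
        ctq = cell$ctq, sex = cell$sex,
        n_pairs = fit$n_pairs, n_features = fit$n_features,
        mean_accuracy = fit$mean_accuracy, se_accuracy = fit$se_accuracy,
        K = imp$K, error = NA_character_, stringsAsFactors = FALSE)
      det <- list(accuracy = fit$accuracy, lambda = fit$lambda,
                  important = imp, important_indices = imp$indices,
                  enrichment = enr, sample = sample)
      if (keep_fits) det$fit <- fit
      if (!is.null(ckpt)) {
        jsonlite::write_json(list(summary = summary_row, accuracy = fit$accuracy,
                                  lambda = fit$lambda,
                                  important_indices = imp$indices),
                             ckpt, auto_unbox = TRUE, digits = NA)
      }
      list(summary = summary_row, detail = det)
    }, error = function(e) {
      list(summary = data.frame(
        phenotype = cell$phenotype, modality = cell$modality,
        ctq = cell$ctq, sex = cell$sex, n_pairs = NA_integer_,
        n_features = NA_integer_, mean_accuracy = NA_real_,
        se_accuracy = NA_real_, K = NA_integer_,
        error = conditionMessage(e), stringsAsFactors = FALSE),
        detail = list(error = conditionMessage(e)))
    })
    cells[[i]] <- res$summary
    details[[i]] <- res$detail
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(cells = cells, details = details, seed = seed,
                 cohort_seed = cohort$config$seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %d grid cells (seed %d)\n",
              nrow(x$cells), x$seed))
  tab <- x$cells
  tab$mean_accuracy <- round(100 * tab$mean_accuracy, 1)
  tab$se_accuracy <- round(100 * tab$se_accuracy, 1)
  print(tab[, c("phenotype", "modality", "ctq", "sex", "n_pairs",
                "mean_accuracy", "se_accuracy", "K", "error")],
        row.names = FALSE)
  invisible(x)
}

#' Compare important-feature sets across CTQ thresholds
#'
#' For every (phenotype, modality) with both an unthresholded cell and a
#' cell at `tau`, reports the two set sizes, their overlap, and the
#' Jaccard index (four decimals). Missing counterpart cells yield rows of
#' `NA` rather than being dropped.
#'
#' @param report an `experiment_report`.
#' @param tau the CTQ threshold to compare against "none" (default 0.4).
#' @return Data frame with columns phenotype, modality, K_none, K_tau,
#'   overlap, jaccard.
#' @export
compare_thresholds <- function(report, tau = 0.4) {
  stopifnot(inherits(report, "experiment_report"))
  cells <- report$cells
  combos <- unique(cells[, c("phenotype", "modality")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ph <- combos$phenotype[i]; mo <- combos$modality[i]
    i_none <- which(cells$phenotype == ph & cells$modality == mo & is.na(cells$ctq))
    i_tau <- which(cells$phenotype == ph & cells$modality == mo &
                     !is.na(cells$ctq) & cells$ctq == tau)
    row <- data.frame(phenotype = ph, modality = mo, K_none = NA_integer_,
                      K_tau = NA_integer_, overlap = NA_integer_,
                      jaccard = NA_real_, stringsAsFactors = FALSE)
    if (length(i_none) == 1L && length(i_tau) == 1L) {
      a <- report$details[[i_none]]$important_indices
      b <- report$details[[i_tau]]$important_indices
      if (!is.null(a) && !is.null(b)) {
        row$K_none <- length(a)
        row$K_tau <- length(b)
        row$overlap <- length(intersect(a, b))
        # half-up rounding to four decimals, the convention of printed tables
        row$jaccard <- floor(jaccard(a, b) * 1e4 + 0.5) / 1e4
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Accuracy correlations across grid cells
#'
#' Pearson correlations (with two-sided p-values) of the per-cell mean
#' test accuracy against the case count and against the number of
#' important features, computed per modality across phenotypes and CTQ
#' thresholds.
#'
#' @param report an `experiment_report`.
#' @return Data frame with one row per modality: `r_size`, `p_size`
#'   (accuracy vs sample size), `r_k`, `p_k` (accuracy vs K), and the
#'   number of cells used.
#' @export
accuracy_correlations <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  cells <- report$cells[!is.na(report$cells$mean_accuracy), , drop = FALSE]
  out <- lapply(unique(cells$modality), function(mo) {
    sub <- cells[cells$modality == mo, , drop = FALSE]
    row <- data.frame(modality = mo, n_cells = nrow(sub),
                      r_size = NA_real_, p_size = NA_real_,
                      r_k = NA_real_, p_k = NA_real_, stringsAsFactors = FALSE)
    if (nrow(sub) < 3L) {
      warning("fewer than 3 cells for modality ", mo,
              "; correlation is degenerate")
      if (nrow(sub) == 2L) {
        row$r_size <- sign(stats::cor(sub$mean_accuracy, sub$n_pairs))
        row$r_k <- sign(stats::cor(sub$mean_accuracy, sub$K))
      }
      return(row)
    }
    if (stats::sd(sub$n_pairs) == 0 || stats::sd(sub$mean_accuracy) == 0) {
      warning("zero variance in accuracy or sample size for modality ", mo)
    } else {
      ct <- stats::cor.test(sub$mean_accuracy, sub$n_pairs)
      row$r_size <- unname(ct$estimate); row$p_size <- ct$p.value
    }
    if (stats::sd(sub$K) == 0 || stats::sd(sub$mean_accuracy) == 0) {
      warning("zero variance in accuracy or K for modality ", mo)
    } else {
      ct <- stats::cor.test(sub$mean_accuracy, sub$K)
      row$r_k <- unname(ct$estimate); row$p_k <- ct$p.value
    }
    row
  })
  do.call(rbind, out)
}
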