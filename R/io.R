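#' Write a cohort to a plain-text directory layout
#'
#' Layout: `subjects.tsv` (one row per subject), `manifest.json` (the full
#' configuration and seed), and optional per-modality directories of
#' per-subject square connectome matrices as tab-delimited text.
#'
#' @param cohort a `conn_cohort`.
#' @param dir output directory (created if needed).
#' @param functional,structural logical: also write the simulated
#'   connectome matrices (default `FALSE`; matrices can always be
#'   re-simulated from the manifest).
#' @param ids subject subset for matrix writing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, functional = FALSE, structural = FALSE,
                         ids = NULL) {
  stopifnot(inherits(cohort, "conn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  manifest <- unclass(cfg)
  manifest$calib <- NULL  # derived constants, recomputed on read
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_mats <- function(arr, sub) {
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    for (id in dimnames(arr)[[3]]) {
      utils::write.table(arr[, , id], file.path(d, paste0(id, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  if (functional) {
    conn <- simulate_functional_cohort(cohort, ids)
    write_mats(conn$corr, "corr")
    write_mats(conn$pcorr, "pcorr")
  }
  if (structural) {
    conn <- simulate_structural_cohort(cohort, ids)
    for (ch in names(conn)) write_mats(conn[[ch]], ch)
  }
  invisible(dir)
}

#' Read a cohort from the on-disk layout
#'
#' Reconstructs the `conn_cohort` from `subjects.tsv` and `manifest.json`
#' written by [write_cohort()]; derived calibration constants are
#' recomputed from the manifest.
#'
#' @param dir directory written by [write_cohort()].
#' @return A `conn_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  tb <- man$target_blocks
  if (is.matrix(tb)) tb <- lapply(seq_len(nrow(tb)), function(i) tb[i, ])
  if (is.numeric(tb)) tb <- list(tb)
  man$target_blocks <- tb
  cfg <- cohort_config(
    n_subjects = man$n_subjects, functional_nodes = man$functional_nodes,
    structural_nodes = man$structural_nodes,
    subnetwork_sizes = man$subnetwork_sizes,
    subnetwork_labels = man$subnetwork_labels,
    target_blocks = man$target_blocks,
    delta = man$delta, ctq_slope = man$ctq_slope,
    effect_phenotype = man$effect_phenotype, ts_length = man$ts_length,
    pcor_rho = man$pcor_rho, within_cor = man$within_cor,
    between_cor = man$between_cor,
    structural_channels = man$structural_channels,
    edge_presence = man$edge_presence, reliability = man$reliability,
    delta_s = man$delta_s, structural_target_nodes = man$structural_target_nodes,
    prev_ever = man$prev_ever, prev_severe = man$prev_severe,
    p_current_symptoms = man$p_current_symptoms, episode_rate = man$episode_rate,
    prev_drug = man$prev_drug, prev_narrow = man$prev_narrow,
    female_fraction = man$female_fraction,
    female_case_fraction = man$female_case_fraction,
    exclusion_rate = man$exclusion_rate,
    ctq_liability_cor = man$ctq_liability_cor,
    severe_current_overlap = man$severe_current_overlap, seed = man$seed)
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  subjects$sex <- factor(subjects$sex, levels = c("female", "male"))
  structure(list(subjects = subjects, config = cfg), class = "conn_cohort")
}

#' Read per-subject connectome matrices from a modality directory
#'
#' @param dir directory of `<id>.tsv` square matrices.
#' @param ids optional subject subset (defaults to every file present).
#' @return nodes x nodes x subjects array.
#' @export
read_connectomes <- function(dir, ids = NULL) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  names(files) <- sub("\\.tsv$", "", basename(files))
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(files))
    if (length(missing)) stop("missing matrices for: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    files <- files[ids]
  }
  mats <- lapply(files, function(f)
    as.matrix(utils::read.delim(f, header = FALSE)))
  arr <- simplify2array(mats)
  dimnames(arr) <- list(NULL, NULL, names(files))
  arr
}

#' Write a matched sample as an audit table
#'
#' @param sample a `matched_sample`.
#' @param path output file (tab-delimited).
#' @export
write_matched_sample <- function(sample, path) {
  stopifnot(inherits(sample, "matched_sample"))
  utils::write.table(sample$pairs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a nested CV result to delimited artifacts
#'
#' Writes `accuracies.tsv` (per-model fold labels, chosen lambda,
#' validation and test accuracy), `coefficients.tsv` (features x models),
#' and `run_log.json` (plan seed, fold sizes, lambda per fold, mean
#' accuracy).
#'
#' @param fit a `nested_ridge`.
#' @param dir output directory.
#' @export
write_cv_result <- function(fit, dir) {
  stopifnot(inherits(fit, "nested_ridge"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  folds <- t(vapply(fit$models, function(m) m$fold, numeric(2)))
  acc <- data.frame(outer = folds[, 1], inner = folds[, 2],
                    lambda = fit$lambda, val_accuracy = fit$val_accuracy,
                    test_accuracy = fit$accuracy)
  utils::write.table(acc, file.path(dir, "accuracies.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cf <- coef(fit, type = "matrix")
  utils::write.table(data.frame(feature = rownames(cf), cf,
                                check.names = FALSE),
                     file.path(dir, "coefficients.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(plan_seed = fit$plan$seed,
                            n_outer = fit$plan$n_outer,
                            n_inner = fit$plan$n_inner,
                            n_pairs = fit$n_pairs,
                            phenotype = fit$phenotype,
                            ctq_threshold = fit$ctq_threshold,
                            modality = fit$modality,
                            lambda = fit$lambda,
                            mean_accuracy = fit$mean_accuracy,
                            se_accuracy = fit$se_accuracy),
                       file.path(dir, "run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write enrichment matrices and the tidy long table
#'
#' Emits six aligned tab-delimited 6 x 6 tables (observed, capacity, p, q,
#' tail, beta_norm when present) plus `enrichment_long.tsv`.
#'
#' @param enr a `subnetwork_enrichment`.
#' @param dir output directory.
#' @export
write_enrichment <- function(enr, dir) {
  stopifnot(inherits(enr, "subnetwork_enrichment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, name) {
    utils::write.table(data.frame(subnetwork = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(enr$observed, "observed")
  wt(enr$capacity, "capacity")
  wt(enr$p, "p_values")
  wt(enr$q, "q_values")
  wt(enr$tail, "tail")
  if (!is.null(enr$beta_norm)) wt(enr$beta_norm, "beta_norm")
  utils::write.table(as.data.frame(enr), file.path(dir, "enrichment_long.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a nested key-value configuration file
#'
#' Plain-text YAML; keys mirror [cohort_config()] and [run_experiment()]
#' arguments.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a feature matrix with its JSON sidecar
#'
#' `<prefix>.tsv` holds the subjects x features values (subject ids in the
#' first column); `<prefix>.json` records the edge-space geometry, the
#' kept-feature mask, and per-column provenance.
#'
#' @param fm a `feature_matrix`.
#' @param prefix output path prefix.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(subject_id = fm$subject_ids, fm$values,
                                check.names = FALSE),
                     paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(modality = fm$modality,
                            n_nodes = fm$space$n_nodes,
                            n_edges = fm$space$n_edges,
                            mask = fm$mask,
                            provenance = fm$provenance),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param prefix the path prefix used when writing.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$subject_id
  structure(list(values = vals,
                 subject_ids = tab$subject_id,
                 modality = side$modality,
                 space = edge_space(side$n_nodes),
                 mask = as.integer(side$mask),
                 provenance = as.data.frame(side$provenance)),
            class = "feature_matrix")
}
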