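#' Regularisation path grid
#'
#' Log-spaced ridge penalties; the default grid holds 13 half-decade points
#' from 1e-3 to 1e3.
#'
#' @param min_lambda,max_lambda grid endpoints (positive).
#' @param length number of grid points.
#' @return Ascending numeric vector of penalties.
#' @export
lambda_grid <- function(min_lambda = 1e-3, max_lambda = 1e3, length = 13L) {
  stopifnot(min_lambda > 0, max_lambda >= min_lambda, length >= 1L)
  10^seq(log10(min_lambda), log10(max_lambda), length.out = length)
}

#' Pair-level nested cross-validation plan
#'
#' Assigns each matched pair to one of `n_outer` outer folds and, within
#' each outer-training set, to one of `n_inner` inner folds. Case and
#' control of a pair always travel together, so every training, validation,
#' and test set keeps the 1:1 ratio; fold sizes differ by at most one pair.
#'
#' @param n_pairs number of matched pairs (or a `matched_sample`).
#' @param n_outer outer folds (default 6).
#' @param n_inner inner folds (default 5).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return Object of class `cv_plan`: `outer` (length `n_pairs`) and
#'   `inner` (`n_pairs` x `n_outer` matrix, `NA` where the pair sits in
#'   that outer test fold).
#' @export
cv_plan <- function(n_pairs, n_outer = 6L, n_inner = 5L, seed = 1L) {
  if (inherits(n_pairs, "matched_sample")) n_pairs <- nrow(n_pairs$pairs)
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < n_outer) {
    stop("validation error: need at least ", n_outer, " pairs for ", n_outer,
         " outer folds", call. = FALSE)
  }
  if (n_pairs - ceiling(n_pairs / n_outer) < n_inner) {
    stop("validation error: outer-training sets too small for ", n_inner,
         " inner folds", call. = FALSE)
  }
  with_seed(seed, {
    outer <- sample(rep_len(seq_len(n_outer), n_pairs))
    inner <- matrix(NA_integer_, n_pairs, n_outer)
    for (o in seq_len(n_outer)) {
      idx <- which(outer != o)
      inner[idx, o] <- sample(rep_len(seq_len(n_inner), length(idx)))
    }
    structure(list(outer = outer, inner = inner, n_outer = n_outer,
                   n_inner = n_inner, seed = as.integer(seed)),
              class = "cv_plan")
  })
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Nested CV plan: %d pairs, %d outer x %d inner folds (seed %d)\n",
              length(x$outer), x$n_outer, x$n_inner, x$seed))
  invisible(x)
}

# Accuracy of +/-1 predictions from a linear score.
score_accuracy <- function(eta, y) mean(ifelse(eta >= 0, 1, -1) == y)

#' Inner-loop penalty selection on one outer-training set
#'
#' For each inner fold, fits the full lambda path on the inner-training
#' rows (z-normalization refitted on those rows only), evaluates
#' classification accuracy on the inner-validation rows, and keeps the
#' model with the highest validation accuracy; ties resolve toward the
#' largest (most regularized) lambda.
#'
#' @param x raw (un-normalized) outer-training feature matrix.
#' @param y labels aligned with `x` rows.
#' @param inner_fold inner fold id per row (1..n_inner).
#' @param lambda penalty grid.
#' @param tol,max_iter optimizer controls.
#' @return List with one element per inner fold: the chosen `lambda`, the
#'   fitted `model` (a `logistic_ridge` carrying its z-normalization
#'   statistics), the validation accuracy, and the per-lambda accuracies.
#' @export
select_lambda <- function(x, y, inner_fold, lambda = lambda_grid(),
                          tol = 1e-8, max_iter = 100L) {
  x <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  y <- as_pm1(y)
  stopifnot(length(inner_fold) == nrow(x), all(lambda > 0))
  folds <- sort(unique(inner_fold))
  out <- vector("list", length(folds))
  names(out) <- paste0("inner", folds)
  for (m in folds) {
    val <- which(inner_fold == m)
    trn <- which(inner_fold != m)
    if (!length(val)) stop("plan error: empty inner-validation fold ", m, call. = FALSE)
    zn <- fit_znorm(x, rows = trn)
    xt <- apply_znorm(x[trn, , drop = FALSE], zn)
    xv <- apply_znorm(x[val, , drop = FALSE], zn)
    path <- ridge_path(xt, y[trn], lambda, tol = tol, max_iter = max_iter)
    acc <- numeric(length(lambda))
    best <- NULL
    # scan from the largest penalty downward so ties keep the largest lambda
    for (k in order(lambda, decreasing = TRUE)) {
      beta <- path_beta(path, k)
      eta <- drop(path$fits[[k]]$intercept + xv %*% beta)
      acc[k] <- score_accuracy(eta, y[val])
      if (is.null(best) || acc[k] > best$accuracy) {
        best <- list(k = k, beta = beta, accuracy = acc[k])
      }
    }
    fit <- path$fits[[best$k]]
    model <- structure(list(lambda = lambda[best$k],
                            intercept = fit$intercept,
                            coefficients = stats::setNames(best$beta, colnames(x)),
                            grad_norm = fit$grad_norm,
                            iterations = fit$iterations,
                            znorm = zn,
                            train_rows = trn),
                       class = "logistic_ridge")
    out[[paste0("inner", m)]] <- list(lambda = lambda[best$k], model = model,
                                      val_accuracy = best$accuracy,
                                      grid_accuracy = acc)
  }
  out
}

#' Nested cross-validated logistic ridge classification
#'
#' The package's central fitting routine: a pair-level nested
#' `n_outer` x `n_inner` cross-validation (default 6 x 5) of the logistic
#' ridge classifier over a matched case-control sample. For every outer
#' fold, each of the inner folds selects its own penalty from `lambda` by
#' validation accuracy (z-normalization refitted on each inner-training
#' set); every inner-optimal model is then evaluated on the untouched outer
#' test fold, giving `n_outer * n_inner` (default 30) models and test
#' accuracies. Outer-test subjects never enter z-normalization or penalty
#' selection.
#'
#' @param features a `feature_matrix` (or matrix with subject-id rownames)
#'   covering all matched subjects; raw, un-normalized values.
#' @param sample a `matched_sample`; cases are labelled +1, controls -1.
#' @param plan optional [cv_plan()]; built from `seed` when omitted.
#' @param lambda penalty grid (default [lambda_grid()]).
#' @param n_outer,n_inner fold counts used when `plan` is omitted.
#' @param seed seed for the fold plan.
#' @param tol,max_iter optimizer controls.
#' @return Object of class `nested_ridge`: 30 fitted models (each carrying
#'   its fold labels, chosen lambda, and z-normalization statistics), the
#'   30 outer-test accuracies, their mean and standard error, and the plan.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(600, seed = 7))
#' ms <- match_cases(cohort, "ever", n_pairs = 40)
#' conn <- simulate_functional_cohort(cohort, matched_ids(ms))
#' fm <- connectome_features(conn$corr, "corr")
#' fit <- nested_ridge(fm, ms, seed = 7)
#' print(fit)
#' }
#' @export
nested_ridge <- function(features, sample, plan = NULL, lambda = lambda_grid(),
                         n_outer = 6L, n_inner = 5L, seed = 1L,
                         tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(sample, "matched_sample"))
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  ids <- c(sample$pairs$case_id, sample$pairs$control_id)
  missing <- setdiff(ids, rownames(x))
  if (length(missing)) {
    stop("alignment error: subjects missing from the feature matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "", call. = FALSE)
  }
  n_pairs <- nrow(sample$pairs)
  plan <- plan %||% cv_plan(n_pairs, n_outer = n_outer, n_inner = n_inner, seed = seed)
  stopifnot(inherits(plan, "cv_plan"), length(plan$outer) == n_pairs)

  # subject-level bookkeeping: each pair contributes one case and one control
  subj_ids <- c(sample$pairs$case_id, sample$pairs$control_id)
  subj_pair <- rep(seq_len(n_pairs), 2L)
  subj_y <- rep(c(1, -1), each = n_pairs)
  xs <- x[subj_ids, , drop = FALSE]

  models <- list()
  acc <- val_acc <- lam <- numeric(0)
  for (o in seq_len(plan$n_outer)) {
    test_subj <- which(plan$outer[subj_pair] == o)
    train_subj <- which(plan$outer[subj_pair] != o)
    inner_fold <- plan$inner[subj_pair[train_subj], o]
    sel <- select_lambda(xs[train_subj, , drop = FALSE], subj_y[train_subj],
                         inner_fold, lambda = lambda, tol = tol,
                         max_iter = max_iter)
    for (m in seq_along(sel)) {
      model <- sel[[m]]$model
      model$fold <- c(outer = o, inner = m)
      model$train_ids <- subj_ids[train_subj][model$train_rows]
      model$train_rows <- NULL
      eta <- predict(model, xs[test_subj, , drop = FALSE], type = "link")
      a <- score_accuracy(eta, subj_y[test_subj])
      models[[length(models) + 1L]] <- model
      acc <- c(acc, a)
      val_acc <- c(val_acc, sel[[m]]$val_accuracy)
      lam <- c(lam, sel[[m]]$lambda)
    }
  }
  structure(list(models = models,
                 accuracy = acc,
                 val_accuracy = val_acc,
                 lambda = lam,
                 mean_accuracy = mean(acc),
                 se_accuracy = stats::sd(acc) / sqrt(length(acc)),
                 plan = plan,
                 n_pairs = n_pairs,
                 phenotype = sample$phenotype,
                 ctq_threshold = sample$ctq_threshold,
                 n_features = ncol(xs),
                 provenance = if (inherits(features, "feature_matrix"))
                   features$provenance else NULL,
                 modality = if (inherits(features, "feature_matrix"))
                   features$modality else NA_character_),
            class = "nested_ridge")
}

#' @export
print.nested_ridge <- function(x, ...) {
  cat(sprintf("Nested %dx%d cross-validated logistic ridge\n",
              x$plan$n_outer, x$plan$n_inner))
  if (!is.na(x$phenotype)) {
    cat(sprintf("  phenotype: %s%s, modality: %s\n", x$phenotype,
                if (!is.na(x$ctq_threshold))
                  sprintf(" (CTQ >= %g)", x$ctq_threshold) else "",
                x$modality))
  }
  cat(sprintf("  %d pairs, %d features, %d models\n",
              x$n_pairs, x$n_features, length(x$models)))
  cat(sprintf("  mean test accuracy: %.1f%% (SE %.1f%%), chance 50%%\n",
              100 * x$mean_accuracy, 100 * x$se_accuracy))
  invisible(x)
}

#' @export
summary.nested_ridge <- function(object, ...) {
  outer <- vapply(object$models, function(m) m$fold[["outer"]], numeric(1))
  tab <- data.frame(outer_fold = sort(unique(outer)))
  tab$mean_test_accuracy <- vapply(tab$outer_fold, function(o)
    mean(object$accuracy[outer == o]), numeric(1))
  tab$mean_val_accuracy <- vapply(tab$outer_fold, function(o)
    mean(object$val_accuracy[outer == o]), numeric(1))
  tab$median_lambda <- vapply(tab$outer_fold, function(o)
    stats::median(object$lambda[outer == o]), numeric(1))
  structure(list(folds = tab,
                 mean_accuracy = object$mean_accuracy,
                 se_accuracy = object$se_accuracy,
                 lambda_table = table(object$lambda)),
            class = "summary.nested_ridge")
}

#' @export
print.summary.nested_ridge <- function(x, ...) {
  cat("Per-outer-fold summary (accuracies in %):\n")
  tab <- x$folds
  tab$mean_test_accuracy <- round(100 * tab$mean_test_accuracy, 1)
  tab$mean_val_accuracy <- round(100 * tab$mean_val_accuracy, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall: %.1f%% +/- %.1f%% (SE over %d models)\n",
              100 * x$mean_accuracy, 100 * x$se_accuracy, nrow(x$folds) * 5))
  cat("Chosen lambda frequencies:\n")
  print(x$lambda_table)
  invisible(x)
}

#' Coefficients of a nested CV fit
#'
#' @param object a `nested_ridge`.
#' @param type `"matrix"` for the features x models coefficient matrix, or
#'   `"mean"` for the per-feature arithmetic mean over the models.
#' @param ... unused.
#' @export
coef.nested_ridge <- function(object, type = c("matrix", "mean"), ...) {
  type <- match.arg(type)
  mat <- vapply(object$models, function(m) m$coefficients,
                numeric(object$n_features))
  colnames(mat) <- vapply(object$models, function(m)
    sprintf("o%d_i%d", m$fold[["outer"]], m$fold[["inner"]]), character(1))
  if (type == "mean") rowMeans(mat) else mat
}

#' Ensemble prediction from a nested CV fit
#'
#' Averages the predicted case probability over the 30 fold models, each
#' standardizing the input with its own training statistics.
#'
#' @param object a `nested_ridge`.
#' @param newx raw feature matrix on the model's feature columns.
#' @param type `"prob"` (mean probability) or `"class"` (+/-1 at 0.5).
#' @param ... unused.
#' @export
predict.nested_ridge <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newx <- if (inherits(newx, "feature_matrix")) newx$values else as.matrix(newx)
  probs <- vapply(object$models, function(m) predict(m, newx, type = "prob"),
                  numeric(nrow(newx)))
  if (nrow(newx) == 1L) probs <- matrix(probs, nrow = 1L)
  p <- rowMeans(probs)
  if (type == "class") ifelse(p >= 0.5, 1, -1) else p
}

#' Accuracy plot of a nested CV fit
#'
#' Strip chart of the 30 outer-test accuracies grouped by outer fold, with
#' the overall mean and the 50% chance level marked.
#'
#' @param x a `nested_ridge`.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.nested_ridge <- function(x, ...) {
  outer <- vapply(x$models, function(m) m$fold[["outer"]], numeric(1))
  graphics::stripchart(100 * x$accuracy ~ outer, vertical = TRUE,
                       method = "jitter", pch = 19,
                       xlab = "outer fold", ylab = "test accuracy (%)", ...)
  graphics::abline(h = 100 * x$mean_accuracy, lty = 2)
  graphics::abline(h = 50, col = "grey60")
  invisible(x)
}
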