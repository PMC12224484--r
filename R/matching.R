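#' Remove subjects with comorbid-disorder exclusions
#'
#' Excluded subjects are removed from both case and control candidacy
#' before any matching.
#'
#' @param subjects a `conn_cohort` or subjects data frame with an
#'   `excluded` column.
#' @return The subjects data frame without excluded rows.
#' @export
exclude_comorbid <- function(subjects) {
  if (inherits(subjects, "conn_cohort")) subjects <- subjects$subjects
  subjects[!subjects$excluded, , drop = FALSE]
}

#' Restrict cases by childhood-trauma score
#'
#' Keeps cases with `ctq >= tau` (inclusive). `tau = NULL` is the identity
#' ("no threshold"). Applied to cases only, before matching, so the matched
#' sample always keeps its 1:1 ratio.
#'
#' @param cases data frame of case subjects.
#' @param tau threshold in \[0, 1\], or `NULL` for none.
#' @return The filtered cases.
#' @export
apply_ctq_threshold <- function(cases, tau = NULL) {
  if (is.null(tau) || (is.character(tau) && identical(tolower(tau), "none"))) {
    return(cases)
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("validation error: `tau` must be NULL or a number in [0, 1]", call. = FALSE)
  }
  cases[cases$ctq >= tau, , drop = FALSE]
}

#' Greedy 1-to-1 sex-exact nearest-neighbour matching
#'
#' Cases are processed in ascending id order; each receives the unused
#' same-sex control minimizing
#' `|age difference| / sd(age) + |ICV difference| / sd(icv)` (standard
#' deviations taken over the full control pool), ties broken by ascending
#' control id. Matching is without replacement, so every control is used at
#' most once. The procedure is deterministic and invariant to the input
#' order of the pool.
#'
#' @param cases data frame of case subjects (id, sex, age, icv).
#' @param control_pool data frame of candidate controls, disjoint from the
#'   cases and free of any phenotype flag.
#' @param phenotype optional phenotype name recorded in the result.
#' @param ctq_threshold optional CTQ threshold recorded in the result.
#' @return Object of class `matched_sample`: data frame `pairs` with
#'   case/control ids, their age and ICV differences and shared sex, plus
#'   metadata.
#' @export
match_one_to_one <- function(cases, control_pool, phenotype = NA_character_,
                             ctq_threshold = NULL) {
  if (nrow(cases) == 0L) stop("matching error: no cases to match", call. = FALSE)
  if (nrow(control_pool) == 0L) {
    stop("matching error: empty control pool", call. = FALSE)
  }
  if (any(cases$id %in% control_pool$id)) {
    stop("matching error: control pool overlaps the case set", call. = FALSE)
  }
  cases <- cases[order(cases$id), , drop = FALSE]
  control_pool <- control_pool[order(control_pool$id), , drop = FALSE]
  sd_age <- stats::sd(control_pool$age)
  sd_icv <- stats::sd(control_pool$icv)
  if (!is.finite(sd_age) || sd_age == 0) sd_age <- 1
  if (!is.finite(sd_icv) || sd_icv == 0) sd_icv <- 1

  used <- logical(nrow(control_pool))
  out <- vector("list", nrow(cases))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    avail <- which(!used & control_pool$sex == cs$sex)
    if (!length(avail)) {
      stop("matching-exhausted error: no unused ", as.character(cs$sex),
           " control left for case ", cs$id, call. = FALSE)
    }
    d <- abs(control_pool$age[avail] - cs$age) / sd_age +
      abs(control_pool$icv[avail] - cs$icv) / sd_icv
    pick <- avail[which.min(d)]  # pool sorted by id, so ties -> smallest id
    used[pick] <- TRUE
    out[[k]] <- data.frame(case_id = cs$id,
                           control_id = control_pool$id[pick],
                           sex = as.character(cs$sex),
                           age_diff = control_pool$age[pick] - cs$age,
                           icv_diff = control_pool$icv[pick] - cs$icv,
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  structure(list(pairs = pairs,
                 phenotype = phenotype,
                 ctq_threshold = if (is.null(ctq_threshold)) NA_real_ else ctq_threshold),
            class = "matched_sample")
}

#' Build a matched case-control sample for one phenotype
#'
#' End-to-end sample construction: drop excluded subjects, define cases by
#' the phenotype flag (optionally CTQ-thresholded, optionally capped at
#' `n_pairs` cases in ascending id order), define the control pool as
#' subjects with no phenotype flag at all, and run sex-exact
#' nearest-neighbour matching.
#'
#' @param cohort a `conn_cohort` or subjects data frame.
#' @param phenotype one of `drug`, `ever`, `ever_severe`, `current`,
#'   `recurrent`, `mdd_narrow`.
#' @param ctq_threshold CTQ threshold applied to cases, or `NULL`.
#' @param sex `"all"` (default), `"female"`, or `"male"`: restrict the whole
#'   sample to one sex before matching.
#' @param n_pairs optional cap on the number of case-control pairs.
#' @return A `matched_sample`.
#' @export
match_cases <- function(cohort, phenotype, ctq_threshold = NULL, sex = "all",
                        n_pairs = NULL) {
  subjects <- if (inherits(cohort, "conn_cohort")) cohort$subjects else cohort
  phenos <- c("drug", "ever", "ever_severe", "current", "recurrent", "mdd_narrow")
  stopifnot(phenotype %in% phenos)
  subjects <- exclude_comorbid(subjects)
  if (!identical(sex, "all")) {
    stopifnot(sex %in% c("female", "male"))
    subjects <- subjects[subjects$sex == sex, , drop = FALSE]
  }
  flags <- as.matrix(subjects[phenos])
  cases <- subjects[flags[, phenotype], , drop = FALSE]
  cases <- apply_ctq_threshold(cases, ctq_threshold)
  cases <- cases[order(cases$id), , drop = FALSE]
  if (!is.null(n_pairs)) cases <- utils::head(cases, n_pairs)
  pool <- subjects[rowSums(flags) == 0L, , drop = FALSE]
  tau <- if (is.null(ctq_threshold) ||
             (is.character(ctq_threshold) && tolower(ctq_threshold) == "none")) {
    NULL
  } else {
    ctq_threshold
  }
  match_one_to_one(cases, pool, phenotype = phenotype, ctq_threshold = tau)
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Matched sample: %d case-control pairs", nrow(x$pairs)))
  if (!is.na(x$phenotype)) cat(sprintf(" [%s]", x$phenotype))
  if (!is.na(x$ctq_threshold)) cat(sprintf(", CTQ >= %g", x$ctq_threshold))
  cat("\n")
  cat(sprintf("  mean |age diff| = %.2f y, mean |ICV diff| = %.0f mm^3, %.0f%% female\n",
              mean(abs(x$pairs$age_diff)), mean(abs(x$pairs$icv_diff)),
              100 * mean(x$pairs$sex == "female")))
  invisible(x)
}

#' @export
as.data.frame.matched_sample <- function(x, ...) x$pairs

#' Subject ids of a matched sample
#'
#' @param sample a `matched_sample`.
#' @return Character vector: all case ids then all control ids.
#' @export
matched_ids <- function(sample) {
  stopifnot(inherits(sample, "matched_sample"))
  c(sample$pairs$case_id, sample$pairs$control_id)
}
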