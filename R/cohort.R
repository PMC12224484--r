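#' Configuration for a synthetic connectome cohort
#'
#' Bundles every tunable of the synthetic cohort generator: cohort size,
#' connectome geometry (functional and structural node counts, the six-way
#' functional subnetwork partition), the planted case-control effect
#' (`delta`, in Fisher-z units, optionally amplified by the childhood-trauma
#' score through `ctq_slope`), phenotype prevalences, and the seed.
#'
#' The six overlapping depression phenotypes are driven by a latent standard
#' normal liability: `ever` is liability above a threshold calibrated to
#' `prev_ever`; the severe tier (liability above the `prev_severe` threshold)
#' splits into `current` (current symptoms present) and `ever_severe`
#' (current symptoms absent, hence disjoint from `current` unless
#' `severe_current_overlap = TRUE`); `recurrent` requires `ever` plus at
#' least two depressive episodes; `drug` and `mdd_narrow` are
#' liability-dependent Bernoulli draws. Thresholds are sex-specific so that
#' the female share among cases matches `female_case_fraction` while the
#' liability stays standard normal overall.
#'
#' The childhood-trauma (CTQ) score in \[0, 1\] is a zero-inflated Beta
#' coupled to liability through a Gaussian copula with correlation
#' `ctq_liability_cor`. The marginal is calibrated at configuration time so
#' that, among `ever` cases, the thresholds 0.2 / 0.4 / 0.6 sit at
#' approximately the 50th / 70th / 80th case percentiles.
#'
#' @param n_subjects number of subjects to generate (positive integer).
#' @param functional_nodes number of functional network nodes (default 55).
#' @param structural_nodes number of structural network nodes (default 85).
#' @param subnetwork_sizes six positive integers summing to
#'   `functional_nodes`; sizes of the functional subnetworks.
#' @param subnetwork_labels labels of the six subnetworks.
#' @param target_blocks list of length-2 vectors (labels or indices) naming
#'   the subnetwork blocks that carry the planted case-control effect.
#' @param delta planted case-control shift of the target-block edges, on the
#'   Fisher-z correlation scale (non-negative).
#' @param ctq_slope multiplicative amplification of `delta` per unit CTQ
#'   score for case subjects (`delta * (1 + ctq_slope * ctq)`).
#' @param effect_phenotype phenotype flag that defines "case" for the
#'   planted connectome effect.
#' @param ts_length number of simulated time points per functional scan.
#' @param pcor_rho Tikhonov ridge strength used when inverting the sample
#'   correlation matrix for partial correlations (default 0.5).
#' @param within_cor,between_cor base within- and between-subnetwork
#'   correlation of the functional block covariance.
#' @param structural_channels names of the structural weighting channels.
#' @param edge_presence probability that an edge exists in the shared
#'   structural base topology.
#' @param reliability probability that a base-topology edge is observed in a
#'   given subject (in (0, 1]).
#' @param delta_s additive case effect on the log-weights of structural
#'   edges among `structural_target_nodes`.
#' @param structural_target_nodes node indices whose mutual edges carry
#'   `delta_s`.
#' @param prev_ever,prev_severe prevalence of the `ever` flag and of the
#'   severe liability tier (must satisfy `prev_severe < prev_ever`).
#' @param p_current_symptoms probability that a severe-tier subject reports
#'   current symptoms (splitting `current` from `ever_severe`).
#' @param episode_rate Poisson rate of additional depressive episodes among
#'   `ever` cases (episodes are `1 + rpois(episode_rate)`).
#' @param prev_drug,prev_narrow marginal prevalences of the `drug` and
#'   `mdd_narrow` flags.
#' @param female_fraction overall female share (default 1/2).
#' @param female_case_fraction female share among liability-threshold cases
#'   (default 2/3).
#' @param exclusion_rate probability of the comorbid-disorder exclusion flag.
#' @param ctq_liability_cor Gaussian-copula correlation between the CTQ
#'   latent and the liability.
#' @param severe_current_overlap if `TRUE`, `ever_severe` is the whole
#'   severe tier and may overlap `current`; default `FALSE` keeps the two
#'   disjoint (current symptoms absent).
#' @param seed integer seed controlling the whole cohort (covariates,
#'   phenotypes, and every connectome matrix).
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [simulate_functional()]
#' @export
cohort_config <- function(n_subjects,
                          functional_nodes = 55L,
                          structural_nodes = 85L,
                          subnetwork_sizes = c(10L, 9L, 12L, 8L, 8L, 8L),
                          subnetwork_labels = c("SMN", "VN", "EC_AN", "CON", "DMN", "eDMN"),
                          target_blocks = list(c("VN", "VN")),
                          delta = 0.5,
                          ctq_slope = 0,
                          effect_phenotype = "ever",
                          ts_length = 200L,
                          pcor_rho = 0.5,
                          within_cor = 0.3,
                          between_cor = 0.05,
                          structural_channels = c("SC", "FA", "MD", "ICVF", "ISOVF", "OD"),
                          edge_presence = 0.6,
                          reliability = 0.9,
                          delta_s = 0,
                          structural_target_nodes = 1:15,
                          prev_ever = 0.25,
                          prev_severe = 0.10,
                          p_current_symptoms = 0.4,
                          episode_rate = 0.9,
                          prev_drug = 0.05,
                          prev_narrow = 0.065,
                          female_fraction = 0.5,
                          female_case_fraction = 2 / 3,
                          exclusion_rate = 0.02,
                          ctq_liability_cor = 0.35,
                          severe_current_overlap = FALSE,
                          seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || is.na(n_subjects) ||
      n_subjects < 1) {
    stop("configuration error: `n_subjects` must be a positive integer", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  if (length(subnetwork_sizes) != 6L || any(subnetwork_sizes < 1)) {
    stop("configuration error: `subnetwork_sizes` must be six positive integers",
         call. = FALSE)
  }
  if (sum(subnetwork_sizes) != functional_nodes) {
    stop("configuration error: `subnetwork_sizes` must sum to `functional_nodes`",
         call. = FALSE)
  }
  stop_if_not_scalar_number(delta, "delta", lower = 0)
  for (p in c(prev_ever = prev_ever, prev_severe = prev_severe,
              prev_drug = prev_drug, prev_narrow = prev_narrow,
              p_current_symptoms = p_current_symptoms,
              female_fraction = female_fraction,
              female_case_fraction = female_case_fraction)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      stop("configuration error: prevalences and proportions must lie in (0, 1)",
           call. = FALSE)
    }
  }
  if (prev_severe >= prev_ever) {
    stop("configuration error: `prev_severe` must be smaller than `prev_ever`",
         call. = FALSE)
  }
  if (!is.numeric(reliability) || reliability <= 0 || reliability > 1) {
    stop("configuration error: `reliability` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(edge_presence) || edge_presence <= 0 || edge_presence > 1) {
    stop("configuration error: `edge_presence` must lie in (0, 1]", call. = FALSE)
  }
  if (abs(ctq_liability_cor) >= 1) {
    stop("configuration error: `ctq_liability_cor` must lie in (-1, 1)", call. = FALSE)
  }
  phenos <- c("drug", "ever", "ever_severe", "current", "recurrent", "mdd_narrow")
  if (!effect_phenotype %in% phenos) {
    stop("configuration error: unknown `effect_phenotype` ", effect_phenotype,
         call. = FALSE)
  }

  cfg <- list(
    n_subjects = n_subjects,
    functional_nodes = as.integer(functional_nodes),
    structural_nodes = as.integer(structural_nodes),
    subnetwork_sizes = as.integer(subnetwork_sizes),
    subnetwork_labels = subnetwork_labels,
    delta = delta, ctq_slope = ctq_slope,
    effect_phenotype = effect_phenotype,
    ts_length = as.integer(ts_length),
    pcor_rho = pcor_rho,
    within_cor = within_cor, between_cor = between_cor,
    structural_channels = structural_channels,
    edge_presence = edge_presence, reliability = reliability,
    delta_s = delta_s,
    structural_target_nodes = as.integer(structural_target_nodes),
    prev_ever = prev_ever, prev_severe = prev_severe,
    p_current_symptoms = p_current_symptoms, episode_rate = episode_rate,
    prev_drug = prev_drug, prev_narrow = prev_narrow,
    female_fraction = female_fraction,
    female_case_fraction = female_case_fraction,
    exclusion_rate = exclusion_rate,
    ctq_liability_cor = ctq_liability_cor,
    severe_current_overlap = severe_current_overlap,
    seed = as.integer(seed),
    phenotypes = phenos
  )
  cfg$target_blocks <- lapply(target_blocks, function(b) {
    if (is.character(b)) b <- match(b, subnetwork_labels)
    b <- as.integer(b)
    if (length(b) != 2L || anyNA(b) || any(b < 1L) || any(b > 6L)) {
      stop("configuration error: each target block must name two of the six subnetworks",
           call. = FALSE)
    }
    sort(b)
  })
  cfg$calib <- calibrate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic connectome cohort configuration\n")
  cat(sprintf("  subjects: %d   seed: %d\n", x$n_subjects, x$seed))
  cat(sprintf("  functional nodes: %d (%s)\n", x$functional_nodes,
              paste(sprintf("%s=%d", x$subnetwork_labels, x$subnetwork_sizes),
                    collapse = ", ")))
  cat(sprintf("  structural nodes: %d, channels: %s\n", x$structural_nodes,
              paste(x$structural_channels, collapse = ", ")))
  blocks <- vapply(x$target_blocks, function(b)
    paste(x$subnetwork_labels[b], collapse = "-"), character(1))
  cat(sprintf("  planted effect: delta = %g (z-scale) in %s; ctq_slope = %g; phenotype = %s\n",
              x$delta, paste(blocks, collapse = ", "), x$ctq_slope,
              x$effect_phenotype))
  invisible(x)
}

# Sex-specific liability thresholds hitting a target prevalence while
# keeping the requested female share among threshold cases.
sex_thresholds <- function(prev, female_case_fraction, female_fraction) {
  c(female = stats::qnorm(1 - female_case_fraction * prev / female_fraction),
    male   = stats::qnorm(1 - (1 - female_case_fraction) * prev / (1 - female_fraction)))
}

# Probability of crossing the liability threshold given the CTQ latent z,
# marginalized over sex.
case_prob_given_latent <- function(z, thr, rho, w) {
  s <- sqrt(1 - rho^2)
  w * stats::pnorm((thr[["female"]] - rho * z) / s, lower.tail = FALSE) +
    (1 - w) * stats::pnorm((thr[["male"]] - rho * z) / s, lower.tail = FALSE)
}

# Solve all derived generator constants: liability thresholds, the
# zero-inflated Beta marginal of the CTQ score (anchored so that 0.2/0.4/0.6
# sit at the 50th/70th/80th percentile among `ever` cases), and intercepts
# of the liability-dependent Bernoulli phenotypes.
calibrate_config <- function(cfg) {
  w <- cfg$female_fraction
  thr1 <- sex_thresholds(cfg$prev_ever, cfg$female_case_fraction, w)
  thr2 <- sex_thresholds(cfg$prev_severe, cfg$female_case_fraction, w)
  rho <- cfg$ctq_liability_cor

  # CTQ latent quantiles among cases at the three target case percentiles
  cond_cdf <- function(z) {
    stats::integrate(function(u) stats::dnorm(u) *
                       case_prob_given_latent(u, thr1, rho, w),
                     lower = -8, upper = z, rel.tol = 1e-9)$value / cfg$prev_ever
  }
  zq <- vapply(c(0.5, 0.7, 0.8), function(q) {
    stats::uniroot(function(z) cond_cdf(z) - q, c(-6, 6), tol = 1e-8)$root
  }, numeric(1))
  pop_cdf_targets <- stats::pnorm(zq)  # population CDF at ctq = 0.2, 0.4, 0.6

  # Fit the zero-inflated Beta marginal through the three CDF targets
  xs <- c(0.2, 0.4, 0.6)
  obj <- function(theta) {
    p0 <- stats::plogis(theta[1])
    a <- exp(theta[2]); b <- exp(theta[3])
    sum((p0 + (1 - p0) * stats::pbeta(xs, a, b) - pop_cdf_targets)^2)
  }
  fit <- stats::optim(c(stats::qlogis(0.4), log(0.8), log(2)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  ctq_par <- c(p0 = stats::plogis(fit$par[1]),
               shape1 = exp(fit$par[2]), shape2 = exp(fit$par[3]))

  # Intercepts for the liability-dependent Bernoulli phenotypes
  bern_intercept <- function(prev, slope, sex_coef) {
    marg <- function(a) {
      stats::integrate(function(l) stats::dnorm(l) *
                         (w * stats::plogis(a + slope * l + sex_coef) +
                          (1 - w) * stats::plogis(a + slope * l)),
                       -8, 8, rel.tol = 1e-9)$value - prev
    }
    stats::uniroot(marg, c(-20, 5), tol = 1e-9)$root
  }
  drug_slope <- 2; narrow_slope <- 2.5; sex_coef <- 0.7
  list(thr_ever = thr1, thr_severe = thr2,
       ctq = ctq_par, ctq_fit_sse = fit$value,
       drug = c(intercept = bern_intercept(cfg$prev_drug, drug_slope, sex_coef),
                slope = drug_slope, sex = sex_coef),
       narrow = c(intercept = bern_intercept(cfg$prev_narrow, narrow_slope, sex_coef),
                  slope = narrow_slope, sex = sex_coef))
}

# Zero-inflated Beta quantile transform of a standard normal latent.
ctq_from_latent <- function(z, par) {
  u <- stats::pnorm(z)
  out <- numeric(length(u))
  pos <- u > par[["p0"]]
  out[pos] <- stats::qbeta((u[pos] - par[["p0"]]) / (1 - par[["p0"]]),
                           par[["shape1"]], par[["shape2"]])
  out
}

# Split a CTQ score into five item scores in [0, 1] with the exact mean.
ctq_items <- function(ctq) {
  items <- matrix(0, length(ctq), 5L)
  pos <- which(ctq > 0)
  for (i in pos) {
    total <- 5 * ctq[i]
    w <- stats::rgamma(5L, shape = 2)
    x <- total * w / sum(w)
    # redistribute any mass above the per-item cap of 1
    repeat {
      over <- x > 1
      if (!any(over)) break
      excess <- sum(x[over] - 1)
      x[over] <- 1
      room <- !over & x < 1
      x[room] <- x[room] + excess * (1 - x[room]) / sum(1 - x[room])
    }
    items[i, ] <- x
  }
  items
}

#' Draw subject covariates for a synthetic cohort
#'
#' Generates ids, ages (uniform on 45-80 years), sex, intracranial volume
#' (sex-specific normal, mm^3), the abbreviated childhood-trauma score
#' (zero-inflated Beta in \[0, 1\], equal to the mean of five item scores),
#' and the comorbidity exclusion flag. Uses the current RNG stream; seed it
#' through [generate_cohort()] for reproducibility.
#'
#' @param config a [cohort_config()].
#' @return A data frame with one row per subject.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  sex <- factor(ifelse(stats::runif(n) < config$female_fraction, "female", "male"),
                levels = c("female", "male"))
  icv_mean <- c(female = 1.40e6, male = 1.55e6)
  icv_sd <- c(female = 9e4, male = 1.0e5)
  z_ctq <- stats::rnorm(n)
  ctq <- ctq_from_latent(z_ctq, config$calib$ctq)
  items <- ctq_items(ctq)
  ctq <- rowMeans(items)  # exact item-mean identity, zeros preserved
  subjects <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age = stats::runif(n, 45, 80),
    sex = sex,
    icv = stats::rnorm(n, icv_mean[as.character(sex)], icv_sd[as.character(sex)]),
    ctq = ctq,
    excluded = stats::runif(n) < config$exclusion_rate,
    stringsAsFactors = FALSE
  )
  subjects$ctq_latent <- z_ctq
  colnames(items) <- paste0("ctq_item", 1:5)
  cbind(subjects, items)
}

#' Assign the six overlapping depression phenotypes
#'
#' Draws the latent liability (standard normal, correlated with the
#' childhood-trauma latent) and derives the six flags: `ever` (liability
#' above the sex-specific threshold), `current` (severe tier with current
#' symptoms), `ever_severe` (severe tier, current symptoms absent),
#' `recurrent` (`ever` with at least two episodes), and the
#' liability-dependent `drug` and `mdd_narrow` flags. Excluded subjects
#' carry no flag. Uses the current RNG stream.
#'
#' @param subjects data frame from [generate_covariates()].
#' @param config the matching [cohort_config()].
#' @return `subjects` with liability, episode count, and flag columns added.
#' @export
assign_phenotypes <- function(subjects, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(subjects)
  rho <- config$ctq_liability_cor
  liability <- rho * subjects$ctq_latent + sqrt(1 - rho^2) * stats::rnorm(n)
  cal <- config$calib
  t1 <- unname(cal$thr_ever[as.character(subjects$sex)])
  t2 <- unname(cal$thr_severe[as.character(subjects$sex)])

  ever <- liability > t1
  severe <- liability > t2
  current_symptoms <- stats::runif(n) < config$p_current_symptoms
  current <- severe & current_symptoms
  ever_severe <- if (config$severe_current_overlap) severe else severe & !current_symptoms
  n_episodes <- integer(n)
  n_episodes[ever] <- 1L + stats::rpois(sum(ever), config$episode_rate)
  recurrent <- ever & n_episodes >= 2L
  female <- subjects$sex == "female"
  drug <- stats::runif(n) < stats::plogis(cal$drug[["intercept"]] +
                                            cal$drug[["slope"]] * liability +
                                            cal$drug[["sex"]] * female)
  mdd_narrow <- stats::runif(n) < stats::plogis(cal$narrow[["intercept"]] +
                                                  cal$narrow[["slope"]] * liability +
                                                  cal$narrow[["sex"]] * female)

  flags <- cbind(drug = drug, ever = ever, ever_severe = ever_severe,
                 current = current, recurrent = recurrent,
                 mdd_narrow = mdd_narrow)
  flags[subjects$excluded, ] <- FALSE

  if (n >= 1000L) {
    counts <- colSums(flags)
    if (any(counts == 0L)) {
      stop("generation error: zero cases generated for phenotype(s): ",
           paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
    }
  }
  subjects$liability <- liability
  subjects$current_symptoms <- current_symptoms
  subjects$n_episodes <- n_episodes
  out <- cbind(subjects, as.data.frame(flags))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_covariates()] and [assign_phenotypes()] under the
#' configuration seed. Connectome matrices are simulated separately (and
#' lazily) with [simulate_functional_cohort()] / [simulate_structural_cohort()];
#' per-subject sub-seeds derived from the configuration seed make the
#' matrices identical no matter which subset of subjects is materialized.
#'
#' @param config a [cohort_config()].
#' @return An object of class `conn_cohort`: a list with `subjects` (data
#'   frame) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- with_seed(config$seed, {
    assign_phenotypes(generate_covariates(config), config)
  })
  structure(list(subjects = subjects, config = config), class = "conn_cohort")
}

#' @export
print.conn_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Synthetic connectome cohort: %d subjects (%d excluded)\n",
              nrow(s), sum(s$excluded)))
  counts <- vapply(x$config$phenotypes, function(p) sum(s[[p]]), integer(1))
  cat("  cases:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  female fraction: %.2f; mean CTQ: %.3f\n",
              mean(s$sex == "female"), mean(s$ctq)))
  invisible(x)
}

#' Pairwise phenotype overlap table
#'
#' Cross-tabulates the six case definitions: off-diagonal cell (i, j) is the
#' number of subjects that are cases under both definitions, with the
#' percentage taken relative to the column phenotype's case total; the
#' diagonal holds the cases unique to that phenotype.
#'
#' @param subjects a `conn_cohort` or its `subjects` data frame with the six
#'   flag columns.
#' @return An object of class `phenotype_overlap` with elements `counts`,
#'   `percent` (column percentages, one decimal), `totals`.
#' @export
phenotype_overlap_table <- function(subjects) {
  if (inherits(subjects, "conn_cohort")) subjects <- subjects$subjects
  phenos <- c("drug", "ever", "ever_severe", "current", "recurrent", "mdd_narrow")
  missing <- setdiff(phenos, names(subjects))
  if (length(missing)) {
    stop("phenotype flags not assigned: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  flags <- as.matrix(subjects[phenos]) * 1L
  counts <- t(flags) %*% flags
  storage.mode(counts) <- "integer"
  totals <- diag(counts)
  any_other <- vapply(seq_along(phenos), function(i) {
    others <- flags[, -i, drop = FALSE]
    sum(flags[, i] == 1L & rowSums(others) == 0L)
  }, integer(1))
  diag(counts) <- any_other  # cases unique to each phenotype
  percent <- sweep(counts, 2L, pmax(totals, 1L), "/") * 100
  percent <- round(percent, 1)
  dimnames(counts) <- dimnames(percent) <- list(phenos, phenos)
  names(totals) <- phenos
  structure(list(counts = counts, percent = percent, totals = totals),
            class = "phenotype_overlap")
}

#' @export
print.phenotype_overlap <- function(x, ...) {
  cat("Pairwise phenotype overlap (column percentages in brackets; diagonal = unique cases)\n")
  m <- matrix(sprintf("%d (%.1f%%)", x$counts, x$percent),
              nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  cat("Totals:", paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", "), "\n")
  invisible(x)
}
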