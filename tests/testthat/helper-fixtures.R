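# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# A large covariate-only cohort for calibration checks (no connectomes).
big_cohort <- function() {
  if (is.null(.fixtures$big)) {
    .fixtures$big <- generate_cohort(cohort_config(10000, seed = 421))
  }
  .fixtures$big
}

# A small cohort with matched pairs and simulated functional matrices.
small_fit_inputs <- function() {
  if (is.null(.fixtures$small)) {
    cohort <- generate_cohort(cohort_config(450, delta = 0.5, seed = 77))
    ms <- match_cases(cohort, "ever", n_pairs = 30)
    conn <- simulate_functional_cohort(cohort, matched_ids(ms))
    .fixtures$small <- list(cohort = cohort,
                            sample = ms,
                            features = connectome_features(conn$corr, "corr"))
  }
  .fixtures$small
}

# Symmetric zero-diagonal matrix with given row-major upper-triangle values.
sym_from_upper <- function(n, values) {
  pairs <- t(utils::combn(n, 2))
  m <- matrix(0, n, n)
  m[pairs] <- values
  m + t(m)
}

# Naive hypergeometric tail probabilities by direct summation of the
# probability mass (independent oracle for the block test).
naive_hyper_tail <- function(o, s, k, ne, lower) {
  pm <- function(x) choose(s, x) * choose(ne - s, k - x) / choose(ne, k)
  xs <- if (lower) 0:o else o:k
  sum(vapply(xs, pm, numeric(1)))
}
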