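test_that("functional matrices are symmetric, zero-diagonal and finite", {
  inputs <- small_fit_inputs()
  cohort <- inputs$cohort
  ids <- matched_ids(inputs$sample)[1:6]
  conn <- simulate_functional_cohort(cohort, ids)
  for (k in seq_along(ids)) {
    for (mod in c("corr", "pcorr")) {
      m <- conn[[mod]][, , k]
      expect_identical(m, t(m))
      expect_identical(diag(m), rep(0, nrow(m)))
      expect_true(all(is.finite(m)))
    }
  }
})

test_that("functional simulation is reproducible and subset-invariant", {
  cohort <- small_fit_inputs()$cohort
  ids <- cohort$subjects$id[c(3, 10, 25)]
  a <- simulate_functional_cohort(cohort, ids)
  b <- simulate_functional_cohort(cohort, ids)
  expect_identical(a, b)
  # simulating a superset yields identical per-subject matrices
  sup <- simulate_functional_cohort(cohort, cohort$subjects$id[1:30])
  expect_identical(a$corr[, , ids], sup$corr[, , ids])
  # single-subject entry point agrees with the cohort path
  one <- simulate_functional(cohort$subjects[3, ], cohort$config,
                             seed = connridge:::derive_seed(cohort$config$seed,
                                                            1000000 + 3))
  expect_identical(one$corr, a$corr[, , 1])
})

test_that("null generator shows no case-control block differences", {
  cohort <- generate_cohort(cohort_config(1200, delta = 0, seed = 31))
  s <- exclude_comorbid(cohort)
  cases <- head(s$id[s$ever], 150)
  controls <- head(s$id[!s$ever], 150)
  conn <- simulate_functional_cohort(cohort, c(cases, controls))
  space <- edge_space(55)
  part <- config_partition(cohort$config)
  grp <- as.integer(part$labels)
  vec <- apply(conn$corr, 3, vectorize_upper, space = space)
  block_of <- paste(pmin(grp[space$pairs[, 1]], grp[space$pairs[, 2]]),
                    pmax(grp[space$pairs[, 1]], grp[space$pairs[, 2]]))
  for (b in unique(block_of)) {
    rows <- block_of == b
    case_means <- colMeans(vec[rows, seq_along(cases), drop = FALSE])
    ctrl_means <- colMeans(vec[rows, length(cases) + seq_along(controls),
                               drop = FALSE])
    tt <- stats::t.test(case_means, ctrl_means)
    expect_lt(abs(unname(tt$statistic)), 4)
  }
})

test_that("planted Fisher-z shift is recovered by Monte Carlo", {
  # delta = 0.3 within the VN block; mean case-control z difference on the
  # target edges should land within +/-20% of the planted shift
  cohort <- generate_cohort(cohort_config(2600, delta = 0.3, ctq_slope = 0,
                                          seed = 13))
  s <- exclude_comorbid(cohort)
  cases <- head(s$id[s$ever], 500)
  controls <- head(s$id[!s$ever], 500)
  conn <- simulate_functional_cohort(cohort, c(cases, controls))
  part <- config_partition(cohort$config)
  vn <- which(part$labels == "VN")
  block <- conn$corr[vn, vn, ]
  ut <- upper.tri(block[, , 1])
  edge_vals <- apply(block, 3, function(m) mean(m[ut]))
  diff <- mean(edge_vals[seq_along(cases)]) -
    mean(edge_vals[length(cases) + seq_along(controls)])
  expect_gt(diff, 0.8 * 0.3)
  expect_lt(diff, 1.2 * 0.3)
})

test_that("non-positive-definite base covariance raises a generation error", {
  cfg <- cohort_config(50, within_cor = 0.1, between_cor = 0.6, seed = 2)
  cohort <- generate_cohort(cfg)
  expect_error(simulate_functional(cohort$subjects[1, ], cfg),
               "positive definite")
})

test_that("structural matrices respect topology, symmetry and density", {
  cohort <- generate_cohort(cohort_config(60, seed = 19))
  ids <- cohort$subjects$id[1:12]
  arrs <- simulate_structural_cohort(cohort, ids)
  expect_named(arrs, cohort$config$structural_channels)
  dens <- numeric(0)
  space <- edge_space(cohort$config$structural_nodes)
  for (k in seq_along(ids)) {
    m <- arrs$FA[, , k]
    expect_identical(m, t(m))
    expect_true(all(m >= 0))
    expect_identical(diag(m), rep(0, nrow(m)))
    dens <- c(dens, mean(m[space$pairs] > 0))
  }
  # per-subject density near edge_presence * reliability = 0.54
  expect_true(all(abs(dens - 0.6 * 0.9) < 0.1))
  # channel-correlated weights: same zero pattern across channels
  expect_identical(arrs$FA[, , 1] > 0, arrs$MD[, , 1] > 0)
})

test_that("perfect reliability reduces thresholding to the base topology", {
  cohort <- generate_cohort(cohort_config(30, reliability = 1, seed = 23))
  ids <- cohort$subjects$id[1:9]
  arr <- simulate_structural_cohort(cohort, ids, channels = "SC")$SC
  base <- connridge:::structural_base(cohort$config)
  space <- edge_space(cohort$config$structural_nodes)
  kept <- proportional_threshold(arr, 2 / 3)
  expect_identical(as.integer(kept), which(base$presence[space$pairs]))
})
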