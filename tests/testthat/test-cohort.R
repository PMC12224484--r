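test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(300, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(0), "configuration error")
  expect_error(cohort_config(-5), "configuration error")
  expect_error(cohort_config(100, subnetwork_sizes = c(10, 9, 12, 8, 8, 9)),
               "sum to")
  expect_error(cohort_config(100, delta = -0.1), "delta")
  expect_error(cohort_config(100, reliability = 0), "reliability")
  expect_error(cohort_config(100, prev_ever = 1.2), "configuration error")
  expect_error(cohort_config(100, prev_severe = 0.5, prev_ever = 0.3),
               "prev_severe")
})

test_that("CTQ score is the mean of five items, each in [0, 1]", {
  s <- small_fit_inputs()$cohort$subjects
  items <- as.matrix(s[paste0("ctq_item", 1:5)])
  expect_true(all(items >= 0 & items <= 1))
  expect_true(all(s$ctq >= 0 & s$ctq <= 1))
  expect_equal(rowMeans(items), s$ctq, tolerance = 1e-12)
})

test_that("case CTQ quantiles sit near their calibration targets", {
  # thresholds 0.2/0.4/0.6 at ~50th/70th/80th percentile among ever cases
  s <- big_cohort()$subjects
  cases <- s[s$ever, ]
  q <- 100 * c(mean(cases$ctq <= 0.2), mean(cases$ctq <= 0.4),
               mean(cases$ctq <= 0.6))
  expect_true(all(abs(q - c(50, 70, 80)) <= 5))
})

test_that("phenotype nesting and exclusion invariants hold for all subjects", {
  for (s in list(big_cohort()$subjects, small_fit_inputs()$cohort$subjects)) {
    expect_true(all(s$ever[s$current]))
    expect_true(all(s$ever[s$recurrent]))
    expect_true(all(s$ever[s$ever_severe]))
    expect_false(any(s$ever_severe & s$current))
    flags <- s[c("drug", "ever", "ever_severe", "current", "recurrent",
                 "mdd_narrow")]
    expect_true(all(rowSums(flags[s$excluded, ]) == 0))
  }
})

test_that("liability is standard normal and sex-skewed at the case threshold", {
  s <- big_cohort()$subjects
  expect_lt(abs(mean(s$liability)), 0.05)
  expect_lt(abs(stats::sd(s$liability) - 1), 0.05)
  # roughly 2:1 female:male among threshold cases, 1:1 overall
  expect_lt(abs(mean(s$sex == "female") - 0.5), 0.03)
  fem_cases <- mean(s$sex[s$ever] == "female")
  expect_lt(abs(fem_cases - 2 / 3), 0.05)
})

test_that("all phenotype pairs overlap except the disjoint severe split", {
  ov <- phenotype_overlap_table(big_cohort())
  off <- ov$counts
  diag(off) <- NA
  # ever_severe and current are disjoint by definition (current symptoms
  # absent); every other pair must share cases at default prevalences
  expect_identical(ov$counts["ever_severe", "current"], 0L)
  off["ever_severe", "current"] <- off["current", "ever_severe"] <- NA
  expect_true(all(off >= 1, na.rm = TRUE))
})

test_that("overlap table reproduces worked percentage and edge cases", {
  mk <- function(flags) {
    n <- nrow(flags)
    cbind(data.frame(id = seq_len(n), excluded = FALSE), flags)
  }
  # column total 703 with 460 shared cases -> 65.4% of the column
  n <- 4000
  drug <- c(rep(TRUE, 703), rep(FALSE, n - 703))
  ever <- c(rep(TRUE, 460), rep(FALSE, 703 - 460), rep(TRUE, 500),
            rep(FALSE, n - 703 - 500))
  flags <- data.frame(drug = drug, ever = ever, ever_severe = FALSE,
                      current = FALSE, recurrent = FALSE, mdd_narrow = FALSE)
  ov <- phenotype_overlap_table(mk(flags))
  expect_identical(ov$counts["ever", "drug"], 460L)
  expect_equal(ov$percent["ever", "drug"], 65.4)

  # disjoint case sets: zero off-diagonal, diagonals equal the totals
  flags2 <- data.frame(drug = c(TRUE, FALSE, FALSE), ever = c(FALSE, TRUE, FALSE),
                       ever_severe = FALSE, current = FALSE,
                       recurrent = FALSE, mdd_narrow = c(FALSE, FALSE, TRUE))
  ov2 <- phenotype_overlap_table(mk(flags2))
  off <- ov2$counts; diag(off) <- 0
  expect_true(all(off == 0))
  expect_identical(diag(ov2$counts)[c("drug", "ever", "mdd_narrow")],
                   c(drug = 1L, ever = 1L, mdd_narrow = 1L))

  # identical case sets: overlap = total, 100%, zero unique cases
  flags3 <- data.frame(drug = c(TRUE, TRUE, FALSE), ever = c(TRUE, TRUE, FALSE),
                       ever_severe = FALSE, current = FALSE,
                       recurrent = FALSE, mdd_narrow = FALSE)
  ov3 <- phenotype_overlap_table(mk(flags3))
  expect_identical(ov3$counts["drug", "ever"], 2L)
  expect_equal(ov3$percent["drug", "ever"], 100)
  expect_identical(ov3$counts["drug", "drug"], 0L)
})

test_that("a phenotype with no attainable cases raises a named error", {
  cfg <- cohort_config(1200, prev_drug = 1e-6, seed = 3)
  expect_error(generate_cohort(cfg), "generation error.*drug")
})
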