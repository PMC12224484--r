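test_that("block capacities follow the n_i n_j formula and conserve Ne", {
  s <- block_capacity(node_partition(c(2, 3), c("A", "B")))
  expect_equal(s["A", "A"], 1)
  expect_equal(s["A", "B"], 6)
  expect_equal(s["B", "B"], 3)
  expect_equal(sum(s[upper.tri(s, diag = TRUE)]), choose(5, 2))
  # default six-network split conserves the 55-node edge count
  s6 <- block_capacity(node_partition())
  expect_equal(sum(s6[upper.tri(s6, diag = TRUE)]), 1485)
  # a singleton subnetwork has no within-block edges
  s1 <- block_capacity(node_partition(c(1, 4), c("solo", "rest")))
  expect_equal(s1["solo", "solo"], 0)
})

test_that("observed counts tally each edge into exactly one block", {
  part <- node_partition(c(2, 2, 2), c("a", "b", "c"))
  sp <- edge_space(6)
  expect_true(all(observed_block_counts(integer(0), part, sp) == 0))
  within_a <- edge_index(sp, 1, 2)
  o <- observed_block_counts(rep_len(within_a, 1), part, sp)
  expect_equal(o["a", "a"], 1)
  expect_equal(sum(o[upper.tri(o, diag = TRUE)]), 1)
  # brute-force recount over random subsets
  set.seed(51)
  grp <- as.integer(part$labels)
  for (i in 1:10) {
    idx <- sample(sp$n_edges, sample(0:sp$n_edges, 1))
    o <- observed_block_counts(idx, part, sp)
    manual <- matrix(0, 3, 3)
    for (e in idx) {
      g <- sort(grp[sp$pairs[e, ]])
      manual[g[1], g[2]] <- manual[g[1], g[2]] + 1
    }
    expect_equal(o[upper.tri(o, diag = TRUE)],
                 manual[upper.tri(manual, diag = TRUE)],
                 ignore_attr = TRUE)
    expect_equal(sum(o[upper.tri(o, diag = TRUE)]), length(idx))
  }
  expect_error(observed_block_counts(16L, part, sp), "outside the edge space")
})

test_that("hypergeometric tails match exhaustive enumeration on toys", {
  # Ne=10, S=3, K=3, O=3: expectation 0.9 < 3, upper tail, 1/C(10,3)
  r1 <- hypergeom_block_pvalues(matrix(3), matrix(3), 3, 10)
  expect_equal(r1$p[1, 1], 1 / 120)
  expect_identical(r1$tail[1, 1], "more")
  # Ne=10, S=6, K=3, O=0: expectation 1.8 >= 0, lower tail, C(4,3)/C(10,3)
  r2 <- hypergeom_block_pvalues(matrix(0), matrix(6), 3, 10)
  expect_equal(r2$p[1, 1], 4 / 120)
  expect_identical(r2$tail[1, 1], "fewer")
  # K = 0 draws nothing: lower tail with probability one everywhere
  part <- node_partition(c(2, 2, 2), c("a", "b", "c"))
  enr0 <- subnetwork_enrichment(integer(0), part, edge_space(6))
  expect_true(all(enr0$p == 1))
  expect_true(all(enr0$tail == "fewer"))
  expect_error(hypergeom_block_pvalues(matrix(3), matrix(12), 3, 10),
               "must not exceed")
})

test_that("log-space tails equal naive summation over a small exhaustive grid", {
  # all feasible (S, K, O) for Ne up to 12 (the acceptance suite pushes
  # this to Ne = 21)
  for (ne in 2:12) {
    for (s in 0:ne) {
      for (k in 0:ne) {
        o_min <- max(0, k - (ne - s))
        for (o in o_min:min(s, k)) {
          lower <- o <= k * s / ne
          res <- hypergeom_block_pvalues(matrix(o), matrix(s), k, ne)
          expect_equal(res$p[1, 1], naive_hyper_tail(o, s, k, ne, lower),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("at the exact expectation the lower tail is reported", {
  # Ne=10, S=5, K=4: expectation = 2; O = 2 must use the lower tail
  r <- hypergeom_block_pvalues(matrix(2), matrix(5), 4, 10)
  expect_identical(r$tail[1, 1], "fewer")
  expect_equal(r$p[1, 1], naive_hyper_tail(2, 5, 4, 10, lower = TRUE))
})

test_that("BH adjustment matches the textbook step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(52)
  p <- runif(21)
  # independent implementation of the step-up rule
  ord <- order(p)
  m <- length(p)
  stepup <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q_oracle <- numeric(m)
  q_oracle[ord] <- pmin(stepup, 1)
  expect_equal(bh_adjust(p), q_oracle, tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)))
})

test_that("enrichment results conserve mass and skip empty blocks", {
  part <- node_partition(c(1, 4, 5), c("x", "y", "z"))
  sp <- edge_space(10)
  set.seed(53)
  for (i in 1:5) {
    idx <- sample(sp$n_edges, 12)
    enr <- subnetwork_enrichment(idx, part, sp)
    ut <- upper.tri(enr$capacity, diag = TRUE)
    expect_equal(sum(enr$capacity[ut]), sp$n_edges)
    expect_equal(sum(enr$observed[ut]), 12)
    # the zero-capacity singleton diagonal is excluded from the BH family
    expect_true(is.na(enr$q["x", "x"]))
    fam <- which(ut & enr$capacity > 0)
    expect_equal(enr$q[fam], bh_adjust(enr$p[fam]), ignore_attr = TRUE)
    expect_true(all(enr$q[fam] >= enr$p[fam]))
  }
})

test_that("the block test is conservative under uniform random selection", {
  part <- node_partition()
  sp <- edge_space(55)
  set.seed(54)
  flagged <- total <- 0
  for (i in 1:200) {
    idx <- sample(sp$n_edges, 40)
    enr <- subnetwork_enrichment(idx, part, sp)
    ut <- upper.tri(enr$p, diag = TRUE)
    flagged <- flagged + sum(enr$p[ut] < 0.05)
    total <- total + sum(ut)
  }
  # discrete tails make the test conservative; allow Monte-Carlo slack
  expect_lte(flagged / total, 0.05 + 0.01)
})

test_that("the tidy table and writers expose aligned matrices", {
  part <- node_partition(c(2, 2, 2), c("a", "b", "c"))
  sp <- edge_space(6)
  enr <- subnetwork_enrichment(c(1L, 2L, 6L), part, sp,
                               beta_mean = seq(-0.5, 0.9, by = 0.1))
  df <- as.data.frame(enr)
  expect_identical(nrow(df), 6L)
  expect_true(all(c("observed", "capacity", "p", "q", "tail", "beta_norm")
                  %in% names(df)))
  d <- file.path(tempdir(), "enr_out")
  write_enrichment(enr, d)
  expect_true(all(file.exists(file.path(d, c("observed.tsv", "p_values.tsv",
                                             "q_values.tsv", "beta_norm.tsv",
                                             "enrichment_long.tsv")))))
})
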