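test_that("importance criteria: top-half rank and constant sign in all models", {
  # p = 4, 30 models; feature 1 always dominant and positive
  set.seed(41)
  mat <- matrix(rnorm(4 * 30, sd = 0.1), 4, 30)
  mat[1, ] <- 2 + abs(rnorm(30, sd = 0.1))
  imp <- important_features(mat)
  expect_true(1 %in% imp$indices)
  expect_identical(imp$signs[imp$indices == 1], 1L)
  # one sign flip out of 30 disqualifies a top-ranked feature
  mat2 <- mat
  mat2[1, 17] <- -mat2[1, 17]
  expect_false(1 %in% important_features(mat2)$indices)
  # K can never exceed floor(p/2)
  expect_lte(important_features(mat)$K, 2)
  set.seed(42)
  big <- matrix(rnorm(101 * 30), 101, 30)
  expect_lte(important_features(big)$K, 50)
  # invariance to model ordering
  perm <- sample(30)
  expect_identical(important_features(mat)$indices,
                   important_features(mat[, perm])$indices)
  expect_error(important_features(list(rnorm(4), rnorm(5))),
               "differing feature counts")
})

test_that("iid-noise coefficients yield no important features", {
  # survival probability per feature is about 2 * (1/2)^30 per criterion,
  # so K = 0 in every replicate
  set.seed(43)
  ks <- replicate(100, important_features(matrix(rnorm(100 * 30), 100, 30))$K)
  expect_identical(sum(ks), 0L)
})

test_that("jaccard reproduces the printed worked examples", {
  mk <- function(n_a, n_b, n_both) {
    list(a = seq_len(n_a),
         b = c(seq_len(n_both), n_a + seq_len(n_b - n_both)))
  }
  cases <- list(list(36, 38, 10, 0.1563),
                list(10, 29, 7, 0.2188),
                list(32, 30, 11, 0.2157),
                list(60, 63, 23, 0.2300),
                list(16, 22, 4, 0.1176),
                list(36, 58, 13, 0.1605))
  for (cs in cases) {
    sets <- mk(cs[[1]], cs[[2]], cs[[3]])
    # half-up rounding, the convention of printed tables
    expect_equal(floor(jaccard(sets$a, sets$b) * 1e4 + 0.5) / 1e4, cs[[4]])
    expect_equal(jaccard(sets$a, sets$b), jaccard(sets$b, sets$a))
  }
})

test_that("jaccard obeys its boundary and bound properties", {
  expect_equal(jaccard(1:5, 6:9), 0)
  expect_equal(jaccard(1:5, 1:5), 1)
  expect_equal(jaccard(integer(0), integer(0)), 1)
  set.seed(44)
  for (i in 1:20) {
    a <- sample(100, sample(1:30, 1))
    b <- sample(100, sample(1:30, 1))
    j <- jaccard(a, b)
    expect_gte(j, length(intersect(a, b)) / (length(a) + length(b)))
    expect_identical(j == 1, setequal(a, b))
  }
})

test_that("mean coefficients match a direct summation oracle", {
  m <- matrix(0, 3, 2)
  m[, 1] <- c(1, -1, 2); m[, 2] <- c(-1, 1, 4)
  expect_equal(mean_coefficients(m), c(0, 0, 3))
  set.seed(45)
  mat <- matrix(rnorm(50 * 30), 50, 30)
  oracle <- apply(mat, 1, function(r) sum(r) / length(r))
  expect_equal(mean_coefficients(mat), oracle, tolerance = 1e-12)
  # identical models: mean equals any single model
  same <- matrix(rep(rnorm(10), 5), 10, 5)
  expect_equal(mean_coefficients(same), same[, 1])
})

test_that("block coefficients follow the signed-mass formula", {
  # single important edge with mean coefficient 0.5 out of total |mass| 5
  part <- node_partition(c(2, 3), c("A", "B"))
  sp <- edge_space(5)
  beta <- rep(0.5, 10)  # total absolute mass 5
  e_aa <- edge_index(sp, 1, 2)
  bc <- block_coefficients(beta, e_aa, part, sp)
  expect_equal(bc["A", "A"], 0.1)
  expect_equal(sum(bc != 0), 1)
  # no important features: zero matrix
  expect_equal(block_coefficients(beta, integer(0), part, sp),
               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  # hand-computed 5-node case with mixed signs
  beta2 <- c(0.2, -0.4, 0.1, 0.3, -0.2, 0.1, 0.5, -0.1, 0.2, 0.3)
  imp2 <- c(edge_index(sp, 1, 2),   # A-A: +0.2
            edge_index(sp, 1, 3),   # A-B: -0.4
            edge_index(sp, 4, 5))   # B-B: +0.3
  denom <- sum(abs(beta2))          # 2.4
  bc2 <- block_coefficients(beta2, imp2, part, sp)
  expect_equal(bc2["A", "A"], 0.2 / denom)
  expect_equal(bc2["A", "B"], -0.4 / denom)
  expect_equal(bc2["B", "A"], -0.4 / denom)
  expect_equal(bc2["B", "B"], 0.3 / denom)
  # all-null coefficients: defined as zero with a warning
  expect_warning(z <- block_coefficients(rep(0, 10), e_aa, part, sp),
                 "zero")
  expect_true(all(z == 0))
})

test_that("the important-edge export annotates nodes and subnetworks", {
  part <- node_partition(c(2, 3), c("A", "B"))
  sp <- edge_space(5)
  imp <- structure(list(indices = c(1L, 10L), signs = c(1L, -1L), K = 2L),
                   class = "important_features")
  el <- important_edge_list(imp, part, sp, beta_mean = seq(0.1, 1, by = 0.1))
  expect_identical(el$subnetwork_i, c("A", "B"))
  expect_identical(el$subnetwork_j, c("A", "B"))
  expect_identical(el$node_i, c(1L, 4L))
  expect_identical(el$node_j, c(2L, 5L))
  expect_equal(el$beta_mean, c(0.1, 1))
})
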