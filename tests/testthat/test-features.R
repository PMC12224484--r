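test_that("edge space arithmetic and index map are exact", {
  expect_identical(edge_space(55)$n_edges, 1485L)
  expect_identical(edge_space(85)$n_edges, 3570L)
  sp <- edge_space(6)
  expect_identical(sp$n_edges, 15L)
  # bijection: every pair maps to a unique index matching its row in pairs
  idx <- edge_index(sp, sp$pairs[, 1], sp$pairs[, 2])
  expect_identical(idx, seq_len(sp$n_edges))
  expect_identical(edge_index(sp, 4, 2), edge_index(sp, 2, 4))
})

test_that("vectorization is row-major and inverts exactly", {
  sp3 <- edge_space(3)
  m <- sym_from_upper(3, c(1.5, -2, 7))
  expect_identical(vectorize_upper(m, sp3), c(1.5, -2, 7))
  # round trip on random symmetric matrices
  set.seed(1)
  for (n in c(4, 9, 20)) {
    sp <- edge_space(n)
    v <- rnorm(sp$n_edges)
    expect_equal(vectorize_upper(reconstruct_edges(v, sp), sp), v)
  }
  bad <- m; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(vectorize_upper(bad, sp3), "not symmetric")
  expect_error(vectorize_upper(matrix(0, 4, 4), sp3), "dimensions")
})

test_that("proportional thresholding uses the inclusive ceiling rule", {
  sp <- edge_space(3)
  m_on <- sym_from_upper(3, c(1, 1, 1))
  m_e1 <- sym_from_upper(3, c(1, 0, 0))
  arr <- simplify2array(list(m_on, m_on, m_e1))
  dimnames(arr) <- list(NULL, NULL, c("a", "b", "c"))
  kept <- proportional_threshold(arr, 2 / 3)
  # edge 1 present in 3/3, edges 2-3 in 2/3 (boundary, >= rule): all kept
  expect_identical(as.integer(kept), 1:3)
  arr2 <- simplify2array(list(m_on, m_e1, m_e1 * 0))
  dimnames(arr2) <- list(NULL, NULL, c("a", "b", "c"))
  # edges 2-3 present in only 1/3: dropped
  expect_identical(as.integer(proportional_threshold(arr2, 2 / 3)), 1L)
  # degenerate: single all-nonzero subject at fraction 1 keeps everything
  arr3 <- array(m_on, c(3, 3, 1), dimnames = list(NULL, NULL, "a"))
  expect_identical(as.integer(proportional_threshold(arr3, 1)), 1:3)
  # subject-order invariance and idempotence of the induced mask
  arr_perm <- arr2[, , c(3, 1, 2)]
  expect_identical(proportional_threshold(arr_perm, 2 / 3),
                   proportional_threshold(arr2, 2 / 3))
  expect_error(proportional_threshold(array(0, c(3, 3, 0)), 2 / 3),
               "at least one subject")
})

test_that("modality stacking concatenates features and keeps provenance", {
  set.seed(4)
  mk_arr <- function(n, ids) {
    sims <- lapply(ids, function(i) {
      sp <- edge_space(n)
      reconstruct_edges(rnorm(sp$n_edges), sp)
    })
    arr <- simplify2array(sims)
    dimnames(arr) <- list(NULL, NULL, ids)
    arr
  }
  ids <- c("s1", "s2", "s3")
  f <- connectome_features(mk_arr(10, ids), "corr")          # 45 edges
  s <- connectome_features(mk_arr(8, ids), "FA", mask = c(2, 5, 9))
  st <- stack_modalities(f, s)
  expect_identical(dim(st$values), c(3L, 48L))
  # column just past the functional width is the first structural feature
  expect_identical(st$provenance$modality[46], "FA")
  expect_identical(st$provenance$edge[46], 2L)
  expect_identical(st$values[, 46], s$values[, 1])
  # empty structural mask: stacking is the identity on the values
  s0 <- connectome_features(mk_arr(8, ids), "FA", mask = integer(0))
  expect_identical(stack_modalities(f, s0)$values, f$values)
  # mismatched subjects are rejected with the offending ids
  s_bad <- connectome_features(mk_arr(8, c("s1", "s2", "zz")), "FA")
  expect_error(stack_modalities(f, s_bad), "alignment error.*zz")
})

test_that("z-normalization is train-only and handles degenerate columns", {
  set.seed(9)
  x <- matrix(rnorm(60), 10, 6)
  zn <- fit_znorm(x)
  xt <- apply_znorm(x, zn)
  expect_true(all(abs(colMeans(xt)) < 1e-10))
  expect_equal(apply(xt, 2, sd), rep(1, 6))  # n-1 denominator
  # a held-out row equal to the training mean maps to zeros
  expect_equal(drop(apply_znorm(matrix(zn$mean, 1), zn)), rep(0, 6))
  # constant training column -> all zeros with a warning
  x2 <- cbind(x, 3)
  expect_warning(zn2 <- fit_znorm(x2), "zero-variance")
  expect_true(all(apply_znorm(x2, zn2)[, 7] == 0))
  expect_error(fit_znorm(x[1, , drop = FALSE]), "at least two")
})

test_that("feature matrices round-trip through the sidecar layout", {
  set.seed(31)
  sims <- lapply(c("sA", "sB"), function(i) {
    sp <- edge_space(7)
    reconstruct_edges(rnorm(sp$n_edges), sp)
  })
  arr <- simplify2array(sims)
  dimnames(arr) <- list(NULL, NULL, c("sA", "sB"))
  fm <- connectome_features(arr, "corr", mask = c(1, 4, 20))
  prefix <- file.path(tempdir(), "fm_io", "corr")
  write_feature_matrix(fm, prefix)
  back <- read_feature_matrix(prefix)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_identical(back$mask, fm$mask)
  expect_identical(back$provenance$edge, fm$provenance$edge)
  expect_identical(back$space$n_edges, fm$space$n_edges)
})
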