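# Stage I kernels against enumeration oracles.

hmm_amino <- default_hmm_params("amino")
pf_amino <- default_partition_params("amino")

test_that("default model parameters are valid distributions", {
  expect_equal(sum(hmm_amino$init), 1, tolerance = 1e-12)
  expect_equal(rowSums(hmm_amino$trans), rep(1, 5), tolerance = 1e-12)
  expect_equal(sum(hmm_amino$match_emit), 1, tolerance = 1e-9)
  expect_equal(hmm_amino$match_emit, t(hmm_amino$match_emit))
  expect_equal(sum(hmm_amino$ins_emit), 1, tolerance = 1e-9)
  expect_equal(pf_amino$score, t(pf_amino$score))
})

test_that("pair-HMM posterior matches exhaustive path enumeration", {
  p <- hmm_posterior("A", "A", hmm_amino)
  o <- oracle_hmm_posterior("A", "A", hmm_amino)
  expect_equal(p[2, 2], o[2, 2], tolerance = 1e-9)

  withr::local_seed(11)
  for (k in 1:25) {
    x <- random_protein(sample(1:4, 1))
    y <- random_protein(sample(1:4, 1))
    expect_equal(hmm_posterior(x, y, hmm_amino),
                 oracle_hmm_posterior(x, y, hmm_amino), tolerance = 1e-9)
  }
})

test_that("pair-HMM posterior is transpose-symmetric and row-bounded", {
  withr::local_seed(12)
  for (k in 1:5) {
    x <- random_protein(sample(5:50, 1))
    y <- random_protein(sample(5:50, 1))
    p <- hmm_posterior(x, y, hmm_amino)
    expect_equal(p, t(hmm_posterior(y, x, hmm_amino)), tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1 + 1e-9))
    expect_true(all(rowSums(p) <= 1 + 1e-6))
    expect_true(all(colSums(p) <= 1 + 1e-6))
  }
  expect_error(hmm_posterior("", "ACD"), "empty")
})

test_that("partition posterior matches Boltzmann alignment enumeration", {
  p <- pf_posterior("A", "A", pf_amino)
  o <- oracle_pf_posterior("A", "A", pf_amino)
  expect_equal(p[2, 2], o[2, 2], tolerance = 1e-9)

  withr::local_seed(13)
  for (k in 1:25) {
    x <- random_protein(sample(1:4, 1))
    y <- random_protein(sample(1:4, 1))
    expect_equal(pf_posterior(x, y, pf_amino),
                 oracle_pf_posterior(x, y, pf_amino), tolerance = 1e-9)
  }
})

test_that("partition posterior tends to alignment-counting ratios as beta -> 0", {
  withr::local_seed(14)
  small <- pf_amino
  small$beta <- 1e-9
  for (k in 1:10) {
    x <- random_protein(sample(2:4, 1))
    y <- random_protein(sample(2:4, 1))
    counting <- oracle_pf_posterior(x, y, pf_amino, beta = NULL)
    expect_equal(pf_posterior(x, y, small), counting, tolerance = 1e-6)
  }
  bad <- pf_amino; bad$beta <- 0
  expect_error(pf_posterior("AC", "AC", bad), "beta")
})

test_that("RMS combination follows its closed form", {
  expect_equal(combine_rms(matrix(0), matrix(0))[1], 0)
  expect_equal(combine_rms(matrix(0.6), matrix(0.8))[1], 0.707107,
               tolerance = 1e-6)
  grid <- matrix(seq(0, 1, by = 0.05), 3, 7)
  expect_equal(combine_rms(grid, grid), grid, tolerance = 1e-12)
  expect_error(combine_rms(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("MEA score equals brute-force monotone matching enumeration", {
  expect_equal(mea_score(matrix(0, 4, 4)), 0)
  diag1 <- matrix(0, 4, 4); diag(diag1[-1, -1]) <- 1
  expect_equal(mea_score(diag1), 3)

  withr::local_seed(15)
  for (k in 1:30) {
    p <- random_dense_posterior(sample(2:5, 1), sample(2:5, 1), density = 0.8)
    expect_equal(mea_score(p), oracle_mea(p), tolerance = 1e-9)
    expect_equal(mea_score(t(p)), mea_score(p), tolerance = 1e-12)
  }
})

test_that("pair distance derives from MEA with clamping and symmetry", {
  zero <- matrix(0, 4, 5)
  expect_equal(pair_distance(zero), 1)
  diag1 <- matrix(0, 5, 5); diag(diag1[-1, -1]) <- 1
  expect_equal(pair_distance(diag1), 0)
  withr::local_seed(16)
  p <- random_dense_posterior(3, 4)
  expect_equal(pair_distance(p), 1 - oracle_mea(p) / 3, tolerance = 1e-9)
  expect_equal(pair_distance(p), pair_distance(t(p)), tolerance = 1e-12)
})

test_that("posterior task bundles sparse matrices, transpose, and distance", {
  task <- posterior_task("ACDE", "ACDE")
  expect_lt(task$distance, 0.05)
  expect_identical(task$s_yx, sparse_transpose(task$s_xy))

  p <- combine_rms(hmm_posterior("ACDE", "ACWK"), pf_posterior("ACDE", "ACWK"))
  task2 <- posterior_task("ACDE", "ACWK", tau = 0.01)
  dense <- p; dense[dense < 0.01] <- 0
  expect_equal(densify(task2$s_xy), dense, tolerance = 1e-12)

  adaptive <- posterior_task("ACDE", "ACWK", filter = "adaptive", f = 0.25)
  n_all <- sum(p[-1, -1] > 0)
  expect_equal(length(adaptive$s_xy$val), ceiling(0.25 * n_all))
})

test_that("posterior task output is identical across repeated runs", {
  a <- posterior_task("MKVLAT", "MKILAS")
  b <- posterior_task("MKVLAT", "MKILAS")
  expect_identical(a, b)
})
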