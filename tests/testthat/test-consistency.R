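# Weighted consistency transformation against the dense oracle.

test_that("with two sequences the relaxation is the identity", {
  withr::local_seed(41)
  tab <- random_posterior_table(2)
  w <- c(1, 1)
  r <- relax_pair(1, 2, tab, w)
  expect_equal(r$val, tab[[1, 2]]$val, tolerance = 1e-12)
  expect_identical(r$col, tab[[1, 2]]$col)
  round1 <- consistency_round(tab, w, tau = 0)
  expect_equal(round1[[1, 2]]$val, tab[[1, 2]]$val, tolerance = 1e-12)
})

test_that("sparse relaxation equals the dense oracle cell by cell", {
  withr::local_seed(42)
  for (k in 1:40) {
    n <- sample(3:6, 1)
    tab <- random_posterior_table(n, max_len = 10)
    w <- runif(n, 0.2, 2)
    x <- sample(n, 1)
    y <- sample(setdiff(seq_len(n), x), 1)
    r <- relax_pair(x, y, tab, w)
    expect_equal(densify(r), oracle_relax_dense(x, y, tab, w),
                 tolerance = 1e-9)
    # no fill-in: support is contained in the input support
    expect_true(all(densify(r)[densify(tab[[x, y]]) == 0] == 0))
  }
})

test_that("a full round matches the dense reference and stays consistent", {
  withr::local_seed(43)
  for (k in 1:10) {
    n <- 5
    tab <- random_posterior_table(n, max_len = 9)
    w <- runif(n, 0.5, 1.5)
    tau <- 0.02
    out <- consistency_round(tab, w, tau = tau)
    for (x in 1:(n - 1)) {
      for (y in (x + 1):n) {
        dense <- oracle_relax_dense(x, y, tab, w)
        dense[dense < tau] <- 0
        expect_equal(densify(out[[x, y]]), dense, tolerance = 1e-9)
        expect_identical(densify(out[[y, x]]), t(densify(out[[x, y]])))
        expect_lte(length(out[[x, y]]$val), length(tab[[x, y]]$val))
        expect_silent(validate_sparse(out[[x, y]]))
        expect_true(all(out[[x, y]]$val > 0 & out[[x, y]]$val <= 1 + 1e-6))
      }
    }
  }
})

test_that("a third sequence never resurrects an absent cell", {
  # craft a table where P_xz x P_zy has mass at a cell that P_xy lacks
  p12 <- matrix(0, 3, 3); p12[2, 2] <- 0.9            # only cell (1,1)
  p13 <- matrix(0, 3, 3); p13[2, 2] <- 0.8; p13[3, 3] <- 0.8
  p32 <- matrix(0, 3, 3); p32[2, 2] <- 0.7; p32[3, 3] <- 0.7
  mk <- function(p) sparsify(p, 0)
  tasks <- list(list(s_xy = mk(p12), s_yx = sparse_transpose(mk(p12))),
                list(s_xy = mk(p13), s_yx = sparse_transpose(mk(p13))),
                list(s_xy = mk(p32), s_yx = sparse_transpose(mk(p32))))
  tab <- build_posterior_table(tasks, 3)
  r <- relax_pair(1, 2, tab, c(1, 1, 1))
  d <- densify(r)
  expect_gt(d[2, 2], 0)
  expect_equal(d[3, 3], 0)   # product contributes there, but P_xy lacks it
})

test_that("repetition composes rounds and c = 0 is the identity", {
  withr::local_seed(44)
  tab <- random_posterior_table(4, max_len = 8)
  w <- runif(4, 0.5, 1.5)
  expect_identical(run_consistency(tab, w, c_reps = 0), tab)
  two <- run_consistency(tab, w, c_reps = 2, tau = 0.01)
  manual <- consistency_round(consistency_round(tab, w, tau = 0.01),
                              w, tau = 0.01)
  expect_equal(two, manual, tolerance = 1e-15)
  expect_lte(table_element_count(two), table_element_count(tab))
  expect_error(run_consistency(tab, w, c_reps = -1))
})

test_that("round output does not depend on pair processing order", {
  # snapshot semantics: relaxing (1,2) before or after (3,4) reads the
  # same pre-round table, so consistency_round equals pairwise relax_pair
  withr::local_seed(45)
  tab <- random_posterior_table(5, max_len = 8)
  w <- runif(5, 0.5, 1.5)
  out <- consistency_round(tab, w, tau = 0)
  for (x in 1:4) for (y in (x + 1):5) {
    expect_equal(out[[x, y]]$val, relax_pair(x, y, tab, w)$val,
                 tolerance = 1e-15)
  }
})

test_that("adaptive filtering inside a round keeps the element budget", {
  withr::local_seed(46)
  tab <- random_posterior_table(4, max_len = 10, tau = 0)
  w <- rep(1, 4)
  out <- consistency_round(tab, w, filter = "adaptive", f = 0.4)
  for (x in 1:3) for (y in (x + 1):4) {
    n_in <- length(tab[[x, y]]$val)
    expect_equal(length(out[[x, y]]$val), min(n_in, ceiling(0.4 * n_in)))
  }
})

test_that("an inconsistent table is rejected", {
  withr::local_seed(47)
  tab <- random_posterior_table(3)
  s <- tab[[1, 2]]
  # wrong row count in the stored transpose
  tab[[2, 1]] <- sparsify(random_dense_posterior(s$n_cols + 1, s$n_rows), 0.5)
  expect_error(relax_pair(1, 2, tab, rep(1, 3)), "transpose-consistent")
})
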