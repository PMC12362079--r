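test_that("flat-at-chance cohorts produce no clusters", {
  A <- matrix(0.5, 10, 30)
  res <- cluster_mass_test(A, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0L)
  p <- cluster_depth_test(A, n_perm = 200, seed = 1)
  expect_true(all(p == 1))
})

test_that("exhaustive cluster mass p-values match the brute-force oracle", {
  set.seed(21)
  A <- matrix(0.5 + rnorm(8 * 40, sd = 0.05), 8, 40)
  A[, 12:20] <- A[, 12:20] + 0.05
  res <- cluster_mass_test(A, exhaustive = TRUE)
  oracle <- brute_cluster_mass(A)
  expect_equal(res$clusters$p_fwer, oracle)
  expect_gt(nrow(res$clusters), 0)
  # sampled permutations approximate the exhaustive answer
  res_mc <- cluster_mass_test(A, n_perm = 10000, seed = 5)
  expect_equal(res_mc$clusters$p_fwer, oracle, tolerance = 0.05)
})

test_that("exhaustive cluster depth p-values match the brute-force oracle", {
  set.seed(33)
  A <- matrix(0.5 + rnorm(6 * 12, sd = 0.05), 6, 12)
  A[, 4:9] <- A[, 4:9] + 0.06
  p_pkg <- cluster_depth_test(A, exhaustive = TRUE)
  p_brute <- brute_cluster_depth(A)
  expect_equal(p_pkg, p_brute)
  expect_true(any(p_pkg < 1))
})

test_that("depth-significant timepoints lie inside mass-test clusters", {
  set.seed(12)
  for (rep in 1:3) {
    A <- matrix(0.5 + rnorm(9 * 50, sd = 0.04), 9, 50)
    A[, 15:30] <- A[, 15:30] + 0.04
    mass <- cluster_mass_test(A, n_perm = 500, seed = rep)
    depth <- cluster_depth_test(A, n_perm = 500, seed = rep)
    in_cluster <- rep(FALSE, 50)
    for (i in seq_len(nrow(mass$clusters))) {
      in_cluster[mass$clusters$start_idx[i]:mass$clusters$end_idx[i]] <- TRUE
    }
    expect_true(all(which(depth < 1) %in% which(in_cluster)))
  }
})

test_that("cluster p-values are deterministic, never zero, and monotone in signal", {
  set.seed(44)
  A <- matrix(0.5 + rnorm(10 * 40, sd = 0.04), 10, 40)
  A[, 10:20] <- A[, 10:20] + 0.05
  r1 <- cluster_mass_test(A, n_perm = 300, seed = 9)
  r2 <- cluster_mass_test(A, n_perm = 300, seed = 9)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p_fwer > 0))
  # boosting every subject inside the cluster cannot hurt its p-value
  A_boost <- A
  A_boost[, 10:20] <- A_boost[, 10:20] + 0.05
  main1 <- which.max(r1$clusters$mass)
  r3 <- cluster_mass_test(A_boost, n_perm = 300, seed = 9)
  main3 <- which.max(r3$clusters$mass)
  expect_lte(r3$clusters$p_fwer[main3], r1$clusters$p_fwer[main1])
})

test_that("t-statistic variant forms clusters on the t scale", {
  set.seed(50)
  A <- matrix(0.5 + rnorm(12 * 30, sd = 0.04), 12, 30)
  A[, 8:18] <- A[, 8:18] + 0.06
  rt <- cluster_mass_test(A, threshold = 2, statistic = "t",
                          n_perm = 500, seed = 2)
  expect_gt(nrow(rt$clusters), 0)
  expect_true(all(rt$clusters$p_fwer <= 1))
})

test_that("BH adjustment reproduces the worked step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
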