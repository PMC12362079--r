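test_that("exponential moving standardization follows its recursions", {
  # constant input -> zero output everywhere (init block handles the head)
  const <- matrix(5, 2, 100)
  out <- exponential_moving_standardize(const, init_block = 20)
  expect_true(all(out == 0))
  # f = 1 -> the running mean tracks instantly, output 0 after init block
  x <- matrix(rnorm(300), 3, 100)
  out1 <- exponential_moving_standardize(x, f = 1, init_block = 10)
  expect_true(all(out1[, 11:100] == 0))
  # white noise, long series -> output sd near 1
  set.seed(8)
  long <- matrix(rnorm(20000), 1, 20000)
  outw <- exponential_moving_standardize(long, f = 1e-3, init_block = 75)
  expect_lt(abs(sd(outw[1, 5000:20000]) - 1), 0.1)
})

test_that("flat linear decoder separates high-SNR subjects and not null ones", {
  cfg <- tiny_cfg(species_effect_uv = 60, noise_sd_uv = 5)
  tw <- trialwise_config(decoder = "flat_linear", seed = 2)
  r <- cv_trialwise_accuracy(make_binary_subject(cfg), tw)
  expect_gte(r$accuracy, 0.95)
  cfg0 <- tiny_cfg(species_effect_uv = 0, noise_sd_uv = 5)
  r0 <- cv_trialwise_accuracy(make_binary_subject(cfg0), tw)
  n <- 40
  expect_lt(abs(r0$accuracy - 0.5), 3 * sqrt(0.25 / n))
})

test_that("shuffled-label permutation hits the add-one floor at high SNR", {
  cfg <- tiny_cfg(species_effect_uv = 60, noise_sd_uv = 5)
  tw <- trialwise_config(decoder = "flat_linear", seed = 2)
  r <- shuffled_label_permutation(make_binary_subject(cfg), tw,
                                  n_perm = 200, seed = 6)
  expect_equal(r$p_uncorrected, 1 / 201)
  expect_equal(length(r$surrogate), 200L)
  # surrogate distribution centered near chance
  expect_lt(abs(mean(r$surrogate) - 0.5), 0.05)
  # p can never undercut the add-one bound
  expect_gte(r$p_uncorrected, 1 / (r$n_perm + 1))
})

test_that("shuffles permute labels only and are seed-deterministic", {
  cfg <- tiny_cfg(species_effect_uv = 5, noise_sd_uv = 6)
  ds <- make_binary_subject(cfg)
  checksum <- sum(ds$data)
  tw <- trialwise_config(decoder = "flat_linear", seed = 3)
  r1 <- shuffled_label_permutation(ds, tw, n_perm = 50, seed = 4)
  expect_equal(sum(ds$data), checksum)
  r2 <- shuffled_label_permutation(ds, tw, n_perm = 50, seed = 4)
  expect_identical(r1$surrogate, r2$surrogate)
  r3 <- shuffled_label_permutation(ds, tw, n_perm = 50, seed = 5)
  expect_false(identical(r1$surrogate, r3$surrogate))
})

test_that("cohort significance counts uncorrected and FDR-corrected subjects", {
  mk <- function(p) structure(list(subject_id = "s", comparison = "c",
                                   accuracy = 0.6, surrogate = numeric(0),
                                   p_uncorrected = p, q_fdr = NA, n_perm = 100L,
                                   decoder = "flat_linear", n_folds = 10L),
                              class = "subject_decoding")
  all_null <- cohort_significance(lapply(rep(1, 4), mk))
  expect_equal(all_null$k_uncorrected, 0)
  expect_equal(all_null$k_fdr, 0)
  mixed <- cohort_significance(lapply(c(0.01, 0.2, 0.04), mk))
  expect_equal(mixed$k_uncorrected, 2)
  # BH by hand: q = (0.03, 0.2, 0.06) -> one q <= 0.05
  expect_equal(mixed$q, c(0.03, 0.2, 0.06))
  expect_equal(mixed$k_fdr, 1)
  expect_lte(mixed$k_fdr, mixed$k_uncorrected)
})
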