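test_that("cohort configuration rejects invalid geometry", {
  expect_error(cohort_config(tmin = 0.1), "tmin")
  expect_error(cohort_config(effect_window = c(200, 1200)), "effect_window")
  expect_error(cohort_config(n_trials_per_stimulus = 5), ">= 10")
  expect_error(cohort_config(prevalence_true = 1.2), "prevalence_true")
  expect_error(cohort_config(species_effect_uv = -1), "amplitudes")
  expect_error(cohort_config(effect_channels = c("O1", "XX")), "XX")
})

test_that("generated epochs have the declared shape and labels", {
  cfg <- tiny_cfg()
  s <- generate_subject_epochs(cfg, 1)
  ds <- s$epochs
  n_times_expected <- round((cfg$tmax - cfg$tmin) * cfg$sfreq) + 1
  expect_equal(dim(ds), c(40L, 31L, n_times_expected))
  expect_true(all(is.finite(ds$data)))
  expect_true(all(table(ds$stimulus_id) == 10))
  # default full geometry: endpoint-inclusive axis gives 301 samples
  cfg_full <- cohort_config(n_subjects = 1)
  expect_equal(round((cfg_full$tmax - cfg_full$tmin) * cfg_full$sfreq) + 1, 301)
})

test_that("generation is deterministic given (config, subject)", {
  cfg <- tiny_cfg(seed = 99)
  a <- generate_subject_epochs(cfg, 2)
  b <- generate_subject_epochs(cfg, 2)
  expect_identical(a$epochs$data, b$epochs$data)
  c <- generate_subject_epochs(tiny_cfg(seed = 100), 2)
  expect_false(identical(a$epochs$data, c$epochs$data))
})

test_that("injected pattern scales linearly with the species amplitude", {
  g1 <- generate_subject_epochs(tiny_cfg(species_effect_uv = 2), 1)$ground_truth
  g2 <- generate_subject_epochs(tiny_cfg(species_effect_uv = 4), 1)$ground_truth
  expect_equal(norm(g2$species_pattern, "F"), 2 * norm(g1$species_pattern, "F"))
})

test_that("null configuration leaves class means indistinguishable", {
  cfg <- tiny_cfg(species_effect_uv = 0, identity_effect_uv = 0,
                  noise_sd_uv = 5)
  pvals <- sapply(1:8, function(i) {
    ds <- generate_subject_epochs(cfg, 1 + (i - 1) %% 2)$epochs
    human <- grepl("^human", ds$stimulus_id)
    # pick one in-window timepoint/channel and t-test the class difference
    tt <- which.min(abs(epoch_times(ds, "ms") - 400))
    ch <- match("Oz", ds$channel_names)
    stats::t.test(ds$data[human, ch, tt], ds$data[!human, ch, tt])$p.value
  })
  expect_gt(mean(pvals), 0.2)    # no systematic class separation
})

test_that("strong effect makes classes linearly separable inside the window", {
  cfg <- tiny_cfg(species_effect_uv = 100, noise_sd_uv = 5)
  ds <- generate_subject_epochs(cfg, 1)$epochs
  y <- as.numeric(grepl("^monkey", ds$stimulus_id))
  tt <- which.min(abs(epoch_times(ds, "ms") - 400))
  acc <- ncm_loo_accuracy(ds$data[, , tt], y)
  expect_gte(acc, 0.975)
  t_pre <- which.min(abs(epoch_times(ds, "ms") - (-100)))
  expect_lt(ncm_loo_accuracy(ds$data[, , t_pre], y), 0.8)
})

test_that("cohort carrier counts follow the configured prevalence", {
  cfg <- tiny_cfg()
  cfg$n_subjects <- 8L
  cfg$prevalence_true <- 0.5
  cohort <- generate_cohort(cfg)
  flags <- vapply(cohort$ground_truth, `[[`, TRUE, "has_species_effect")
  expect_equal(sum(flags), 4L)
  expect_equal(flags, c(rep(TRUE, 4), rep(FALSE, 4)))
  # non-carriers get a zero pattern
  expect_true(all(cohort$ground_truth[[8]]$species_pattern == 0))
  expect_true(any(cohort$ground_truth[[1]]$species_pattern != 0))
})
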