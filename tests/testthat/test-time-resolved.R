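test_that("high-SNR subject decodes perfectly inside the effect window", {
  cfg <- tiny_cfg(species_effect_uv = 100, noise_sd_uv = 5)
  ds <- make_binary_subject(cfg)
  dt <- decode_timecourse(ds, seed = 3)
  inside <- dt$time_ms >= 260 & dt$time_ms <= 540   # clear of the ramps
  pre <- dt$time_ms < 0
  expect_true(all(dt$accuracy[inside] >= 0.95))
  expect_lt(mean(abs(dt$accuracy[pre] - 0.5)), 0.15)
  expect_true(all(dt$accuracy >= 0 & dt$accuracy <= 1))
  # agrees with an independent nearest-class-mean oracle at window center
  tt <- which.min(abs(dt$time_ms - 400))
  y <- as.numeric(ds$stimulus_id)
  expect_gte(ncm_loo_accuracy(ds$data[, , tt], y), 0.95)
})

test_that("null subject stays within the binomial chance band", {
  cfg <- tiny_cfg(species_effect_uv = 0, noise_sd_uv = 5,
                  n_trials_per_stimulus = 15)
  ds <- make_binary_subject(cfg)
  dt <- decode_timecourse(ds, seed = 3)
  n <- dim(ds)[1]
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(dt$accuracy) - 0.5), 3 * se)
})

test_that("accuracy series is invariant to label flips, channel order and scale", {
  cfg <- tiny_cfg(species_effect_uv = 8, noise_sd_uv = 5)
  ds <- make_binary_subject(cfg)
  dt <- decode_timecourse(ds, seed = 7)
  # label flip
  flipped <- ds
  flipped$stimulus_id <- as.character(1 - as.numeric(ds$stimulus_id))
  expect_equal(decode_timecourse(flipped, seed = 7)$accuracy, dt$accuracy)
  # channel reordering
  perm <- rev(seq_len(dim(ds)[2]))
  reordered <- eeg_epochs(ds$data[, perm, , drop = FALSE], ds$stimulus_id,
                          ds$session_id, ds$subject_id,
                          ds$channel_names[perm], ds$sfreq, ds$tmin)
  expect_equal(decode_timecourse(reordered, seed = 7)$accuracy, dt$accuracy)
  # common rescaling is absorbed by standardization
  scaled <- ds
  scaled$data <- ds$data * 3.7
  expect_equal(decode_timecourse(scaled, seed = 7)$accuracy, dt$accuracy)
})

test_that("ridge logistic core agrees with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  n <- 120; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X[, 1] - 0.5 * X[, 2] + rnorm(n) > 0)
  lambda <- 1
  fit <- eegmvpa:::.ridge_logit_fit(X, y, lambda)
  # glmnet minimizes (1/n) loglik + (lambda_g/2)||w||^2 for alpha = 0
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(fit$w, as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(fit$b, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("fold-mean accuracy equals pooled accuracy for equal folds", {
  cfg <- tiny_cfg(species_effect_uv = 8, noise_sd_uv = 6)
  ds <- make_binary_subject(cfg)   # 40 trials, 10 folds of 4
  y <- as.numeric(ds$stimulus_id)
  fold <- eegmvpa:::with_seed(1, eegmvpa:::stratified_folds(y, 10))
  expect_true(all(table(fold) == 4))
  acc <- eegmvpa:::.decode_timecourse_core(ds$data, y, as.integer(fold), 1, FALSE)
  # with equal folds, fold-mean = total-correct / total-trials, so each
  # accuracy is a multiple of 1/n
  expect_true(all(abs(acc * 40 - round(acc * 40)) < 1e-9))
})

test_that("Haufe patterns recover a planted linear generative model", {
  set.seed(11)
  n <- 200; n_ch <- 12; n_t <- 5
  a <- rnorm(n_ch)                              # ground-truth pattern
  y <- rep(c(0, 1), each = n / 2)
  X <- array(rnorm(n * n_ch * n_t, sd = 0.3), c(n, n_ch, n_t))
  for (t in 1:n_t) X[, , t] <- X[, , t] + outer(y - 0.5, a)
  ds <- eeg_epochs(X, as.character(y), rep(1L, n), "sim",
                   paste0("ch", 1:n_ch), 5, -0.2)
  fim <- haufe_patterns(ds)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cs <- apply(fim$pattern, 2, cosine, v = a)
  expect_true(all(cs > 0.9))
})

test_that("noise-only Haufe patterns are small and sign-incoherent", {
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  pats <- lapply(1:2, function(s) {
    set.seed(100 + s)
    X <- array(rnorm(120 * 8 * 3), c(120, 8, 3))
    y <- rep(c("0", "1"), each = 60)
    haufe_patterns(eeg_epochs(X, y, rep(1L, 120), "n", paste0("c", 1:8),
                              5, -0.2))$pattern
  })
  expect_lt(abs(cosine(pats[[1]][, 1], pats[[2]][, 1])), 0.8)
})

test_that("group mean and SEM follow their definitions", {
  mk <- function(acc) structure(list(subject_id = "s", comparison = NA,
                                     accuracy = acc, time_ms = c(0, 10),
                                     n_folds = 10),
                                class = "decoding_timeseries")
  g <- group_mean_sem(list(mk(c(0.4, 0.5)), mk(c(0.6, 0.5))))
  expect_equal(g$mean, c(0.5, 0.5))
  expect_equal(g$sem, c(0.1, 0))
  # identical series give zero SEM
  g5 <- group_mean_sem(rep(list(mk(c(0.7, 0.6))), 5))
  expect_equal(g5$sem, c(0, 0))
  expect_error(group_mean_sem(list(mk(c(0.4, 0.5)))), "at least 2")
  bad <- mk(c(0.4, 0.5)); bad$time_ms <- c(0, 20)
  expect_error(group_mean_sem(list(mk(c(0.4, 0.5)), bad)), "time axis")
})
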