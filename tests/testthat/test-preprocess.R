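make_epochs <- function(data, stim, sess = rep(1L, length(stim)),
                        sfreq = 50, tmin = -0.2) {
  eeg_epochs(data, stim, sess, "subX", paste0("ch", seq_len(dim(data)[2])),
             sfreq, tmin)
}

test_that("baseline correction subtracts the pre-stimulus mean", {
  # 2 trials x 1 channel x 41 samples at 50 Hz from -200 ms
  d <- array(0, c(2, 1, 41))
  d[1, 1, ] <- 5                       # constant trial -> all zero
  d[2, 1, ] <- c(rep(2, 10), rep(10, 31))  # baseline 2, peak 10 -> peak 8
  ds <- make_epochs(d, c("human1", "human2"))
  bc <- baseline_correct(ds)
  expect_equal(max(abs(bc$data[1, 1, ])), 0)
  expect_equal(bc$data[2, 1, 41], 8)
  # idempotent
  expect_equal(baseline_correct(bc)$data, bc$data)
  # labels untouched
  expect_identical(bc$stimulus_id, ds$stimulus_id)
  # no pre-stimulus samples -> error
  ds2 <- make_epochs(d, c("human1", "human2"), tmin = 0)
  expect_error(baseline_correct(ds2), "baseline")
})

test_that("balancing downsamples every stimulus to the minimum count", {
  counts <- c(human1 = 90, human2 = 85, monkey1 = 80, monkey2 = 88)
  stim <- rep(names(counts), counts)
  d <- array(rnorm(length(stim) * 2 * 5), c(length(stim), 2, 5))
  ds <- make_epochs(d, stim, tmin = -0.4, sfreq = 10)
  bal <- balance_trials(ds, seed = 4)
  expect_true(all(table(bal$stimulus_id) == 80))
  # determinism and uniqueness
  bal2 <- balance_trials(ds, seed = 4)
  expect_identical(bal$data, bal2$data)
  expect_lte(dim(bal)[1], dim(ds)[1])
  # already balanced input is returned unchanged
  ds_eq <- make_epochs(d[1:40, , , drop = FALSE],
                       rep(names(counts), each = 10), tmin = -0.4, sfreq = 10)
  expect_identical(balance_trials(ds_eq, seed = 1)$data, ds_eq$data)
  # missing stimulus is named in the error
  ds_miss <- subset_trials(ds, ds$stimulus_id != "monkey2")
  expect_error(balance_trials(ds_miss), "monkey2")
})

test_that("balancing preserves relative trial order", {
  stim <- rep(c("human1", "human2", "monkey1", "monkey2"), c(12, 10, 11, 10))
  d <- array(seq_len(length(stim) * 1 * 3), c(length(stim), 1, 3))
  ds <- make_epochs(d, stim, tmin = -0.5, sfreq = 6)
  bal <- balance_trials(ds, seed = 2)
  expect_false(is.unsorted(match(bal$data[, 1, 1], ds$data[, 1, 1])))
})

test_that("session concatenation checks metadata and stacks trials", {
  stim <- rep(c("human1", "human2", "monkey1", "monkey2"), each = 10)
  d1 <- array(rnorm(40 * 2 * 5), c(40, 2, 5))
  d2 <- array(rnorm(40 * 2 * 5), c(40, 2, 5))
  s1 <- make_epochs(d1, stim, rep(1L, 40), tmin = -0.4, sfreq = 10)
  s2 <- make_epochs(d2, stim, rep(2L, 40), tmin = -0.4, sfreq = 10)
  cc <- concatenate_sessions(list(s1, s2))
  expect_equal(dim(cc)[1], 80L)
  expect_true(all(table(cc$stimulus_id) == 20))
  expect_equal(sort(unique(cc$session_id)), c(1L, 2L))
  # identity on singleton list
  expect_identical(concatenate_sessions(list(s1)), s1)
  # mismatched channel order errors with the field name
  s2b <- s2
  s2b$channel_names <- rev(s2b$channel_names)
  expect_error(concatenate_sessions(list(s1, s2b)), "channel_names")
})

test_that("binarize maps stimuli to balanced binary classes", {
  stim <- rep(c("human1", "human2", "monkey1", "monkey2"), each = 80)
  d <- array(rnorm(320 * 2 * 3), c(320, 2, 3))
  ds <- make_epochs(d, stim, tmin = -0.4, sfreq = 5)
  fc <- binarize(ds, comparison("face_categorization"))
  expect_equal(unname(table(fc$stimulus_id)), c(160L, 160L), ignore_attr = TRUE)
  hi <- binarize(ds, comparison("human_individuation"))
  expect_equal(dim(hi)[1], 160L)
  expect_true(all(table(hi$stimulus_id) == 80))
  # degenerate map -> error
  only_h1 <- subset_trials(ds, ds$stimulus_id == "human1")
  expect_error(binarize(only_h1, comparison("human_individuation")), "class")
})

test_that("inclusion rule applies strict thresholds per session layout", {
  expect_true(check_inclusion(matrix(21, 2, 4)))    # two sessions, all > 20
  expect_false(check_inclusion(matrix(c(21, 21, 21, 20), 2, 2)))
  expect_true(check_inclusion(rep(36, 4)))          # one session, all > 35
  expect_false(check_inclusion(c(36, 36, 35, 36)))  # strict >
  expect_false(check_inclusion(rep(35, 4)))
})

test_that("session concatenation commutes with binarization", {
  cfg <- tiny_cfg(n_sessions = 2)
  raw <- generate_subject_epochs(cfg, 1)$epochs
  comp <- comparison("face_categorization")
  sessions <- lapply(sort(unique(raw$session_id)), function(ss) {
    balance_trials(subset_trials(raw, raw$session_id == ss),
                   seed = 5 + ss)
  })
  a <- binarize(concatenate_sessions(sessions), comp)
  b <- concatenate_sessions(lapply(sessions, binarize, comp = comp))
  expect_identical(a$data, b$data)
  expect_identical(a$stimulus_id, b$stimulus_id)
})
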