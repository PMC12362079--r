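#' Configuration for full-trial decoding
#'
#' @param decoder `"flat_linear"` (ridge-penalized logistic regression on
#'   the flattened standardized trial; fast, used throughout the test-scale
#'   simulations) or `"compact_cnn"` (the compact convolutional network).
#' @param cycles Training epochs for the network (default 200).
#' @param batch_size Mini-batch size (default 16).
#' @param n_folds Stratified CV folds (default 10).
#' @param ema_factor Exponential moving standardization factor f
#'   (default 1e-3).
#' @param ema_eps Variance floor eps (default 1e-4).
#' @param init_block Samples standardized jointly by their own mean/sd at
#'   the start of each epoch (default 75).
#' @param lambda L2 penalty of the flat_linear decoder.
#' @param lr Adam learning rate of the network (default 1e-3).
#' @param seed Seed governing folds, initialization, batching and dropout.
#' @return A `trialwise_config` list.
#' @export
trialwise_config <- function(decoder = c("flat_linear", "compact_cnn"),
                             cycles = 200, batch_size = 16, n_folds = 10,
                             ema_factor = 1e-3, ema_eps = 1e-4,
                             init_block = 75, lambda = 1, lr = 1e-3,
                             seed = 1L) {
  decoder <- match.arg(decoder)
  stopifnot(cycles >= 1, batch_size >= 1, n_folds >= 2,
            ema_factor > 0, ema_factor <= 1, ema_eps > 0, init_block >= 1)
  structure(
    list(decoder = decoder, cycles = as.integer(cycles),
         batch_size = as.integer(batch_size), n_folds = as.integer(n_folds),
         ema_factor = ema_factor, ema_eps = ema_eps,
         init_block = as.integer(init_block), lambda = lambda, lr = lr,
         seed = as.integer(seed)),
    class = "trialwise_config"
  )
}

#' Exponential moving standardization of one epoch
#'
#' Causal per-channel running z-scoring: running mean
#' `m_t = (1-f) m_{t-1} + f x_t` and variance
#' `v_t = (1-f) v_{t-1} + f (x_t - m_t)^2`, output
#' `y_t = (x_t - m_t) / max(sqrt(v_t), eps)`. The first `init_block`
#' samples are standardized jointly by their own mean and sd instead (the
#' running statistics have not burnt in yet).
#'
#' @param trial Channels x timepoints matrix in uV.
#' @param f Moving factor.
#' @param eps Variance floor.
#' @param init_block Number of leading samples standardized jointly.
#' @return Standardized channels x timepoints matrix.
#' @export
exponential_moving_standardize <- function(trial, f = 1e-3, eps = 1e-4,
                                           init_block = 75) {
  stopifnot(is.matrix(trial))
  n_times <- ncol(trial)
  init_block <- min(init_block, n_times)
  out <- matrix(0, nrow(trial), n_times)
  m <- trial[, 1]
  v <- rep(0, nrow(trial))
  for (t in seq_len(n_times)) {
    x <- trial[, t]
    m <- (1 - f) * m + f * x
    v <- (1 - f) * v + f * (x - m)^2
    out[, t] <- (x - m) / pmax(sqrt(v), eps)
  }
  if (init_block >= 1) {
    blk <- trial[, seq_len(init_block), drop = FALSE]
    mu <- rowMeans(blk)
    sdv <- sqrt(rowMeans((blk - mu)^2))
    out[, seq_len(init_block)] <- (blk - mu) / pmax(sdv, eps)
  }
  out
}

ems_dataset <- function(ds, cfg) {
  d <- ds$data
  for (tr in seq_len(dim(d)[1L])) {
    d[tr, , ] <- exponential_moving_standardize(
      d[tr, , ], cfg$ema_factor, cfg$ema_eps, cfg$init_block)
  }
  d
}

#' Cross-validated full-trial decoding accuracy
#'
#' Applies exponential moving standardization to every epoch, then runs
#' stratified k-fold cross-validation of the configured decoder on whole
#' trials, reporting the fold-mean test accuracy.
#'
#' @param ds A binary [eeg_epochs].
#' @param cfg A [trialwise_config()].
#' @param comparison_name Optional comparison label carried into the result.
#' @return A `subject_decoding` object (accuracy only; no surrogate
#'   distribution yet).
#' @export
cv_trialwise_accuracy <- function(ds, cfg = trialwise_config(),
                                  comparison_name = NA_character_) {
  y <- binary_labels(ds)
  X <- ems_dataset(ds, cfg)
  fold <- with_seed(derive_seed(cfg$seed, "tw_folds"),
                    stratified_folds(y, cfg$n_folds))
  acc <- trialwise_cv_run(X, y, fold, cfg, ds$sfreq)
  structure(
    list(subject_id = ds$subject_id, comparison = comparison_name,
         accuracy = acc, surrogate = numeric(0), p_uncorrected = NA_real_,
         q_fdr = NA_real_, n_perm = 0L, decoder = cfg$decoder,
         n_folds = cfg$n_folds),
    class = "subject_decoding"
  )
}

# One full CV run on pre-standardized data; shared by the observed run and
# every shuffled-label surrogate (same fold partition, labels permuted).
trialwise_cv_run <- function(X, y, fold, cfg, sfreq) {
  if (cfg$decoder == "flat_linear") {
    d <- dim(X)
    Xf <- matrix(X, d[1L], d[2L] * d[3L])
    .flat_cv_accuracy_core(Xf, y, as.integer(fold), cfg$lambda)
  } else {
    eegnet_cv_accuracy(X, y, fold, cfg, sfreq)
  }
}

#' Shuffled-label permutation test for one subject
#'
#' Re-runs the identical cross-validation procedure `n_perm` times with
#' class labels permuted over all trials (train and test alike), building a
#' surrogate accuracy distribution; the Monte-Carlo p-value uses the
#' add-one rule, one-sided (greater).
#'
#' @param ds A binary [eeg_epochs].
#' @param cfg A [trialwise_config()].
#' @param n_perm Number of label shuffles (study-scale default 1000;
#'   simulations in this package typically use 200).
#' @param seed Seed for the shuffles.
#' @param comparison_name Optional comparison label carried into the result.
#' @return A `subject_decoding` with observed `accuracy`, `surrogate`
#'   distribution and `p_uncorrected`.
#' @export
shuffled_label_permutation <- function(ds, cfg = trialwise_config(),
                                       n_perm = 1000, seed = 1L,
                                       comparison_name = NA_character_) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  y <- binary_labels(ds)
  X <- ems_dataset(ds, cfg)
  fold <- with_seed(derive_seed(cfg$seed, "tw_folds"),
                    stratified_folds(y, cfg$n_folds))
  if (cfg$decoder == "flat_linear") {
    # the fold Gram matrices are label-free, so the observed run and all
    # surrogates share them (identical CV procedure, labels permuted)
    d <- dim(X)
    Xf <- matrix(X, d[1L], d[2L] * d[3L])
    Y <- with_seed(derive_seed(seed, "labelshuffle"), {
      rbind(y, t(vapply(seq_len(n_perm), function(i) sample(y),
                        numeric(length(y)))))
    })
    accs <- .flat_cv_perm_core(Xf, matrix(as.integer(Y), nrow(Y)),
                               as.integer(fold), cfg$lambda)
    observed <- accs[1L]
    surrogate <- accs[-1L]
  } else {
    observed <- trialwise_cv_run(X, y, fold, cfg, ds$sfreq)
    surrogate <- with_seed(derive_seed(seed, "labelshuffle"), {
      vapply(seq_len(n_perm), function(i) {
        trialwise_cv_run(X, sample(y), fold, cfg, ds$sfreq)
      }, 1.0)
    })
  }
  p <- (1 + sum(surrogate >= observed - 1e-12)) / (1 + n_perm)
  structure(
    list(subject_id = ds$subject_id, comparison = comparison_name,
         accuracy = observed, surrogate = surrogate, p_uncorrected = p,
         q_fdr = NA_real_, n_perm = as.integer(n_perm),
         decoder = cfg$decoder, n_folds = cfg$n_folds),
    class = "subject_decoding"
  )
}

#' @export
print.subject_decoding <- function(x, ...) {
  cat("<subject_decoding>", x$subject_id,
      if (!is.na(x$comparison)) paste0("(", x$comparison, ")"),
      "decoder:", x$decoder, "\n")
  cat(sprintf("  accuracy %.3f", x$accuracy))
  if (x$n_perm > 0) {
    cat(sprintf(" | %d surrogates (mean %.3f), p = %.4g",
                x$n_perm, mean(x$surrogate), x$p_uncorrected))
  }
  cat("\n")
  invisible(x)
}

#' Count significant subjects in a cohort
#'
#' Applies the within-subject threshold to the uncorrected p-values and,
#' separately, to BH-FDR-adjusted q-values across participants. The
#' uncorrected count feeds [prevalence_posterior()]; the corrected count is
#' the conventional reporting statistic.
#'
#' @param results List of `subject_decoding` objects for one comparison.
#' @param alpha Significance level (default 0.05).
#' @return List with `k_uncorrected`, `k_fdr`, `n`, `p`, `q`.
#' @export
cohort_significance <- function(results, alpha = 0.05) {
  p <- vapply(results, `[[`, 1.0, "p_uncorrected")
  if (anyNA(p)) stop("results lack permutation p-values")
  q <- bh_fdr(p)
  list(
    k_uncorrected = sum(p <= alpha),
    k_fdr = sum(q <= alpha),
    n = length(p),
    p = p,
    q = q
  )
}
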