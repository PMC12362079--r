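#' Time-resolved decoding of a binary comparison
#'
#' Trains a separate L2-penalized linear logistic classifier for every
#' stimulus-locked timepoint on the cross-channel voltage vector, using
#' stratified k-fold cross-validation, and reports the fold-mean test
#' accuracy per timepoint. The same fold partition is reused at every
#' timepoint so the time series reflects signal dynamics rather than fold
#' noise.
#'
#' By default each channel feature is standardized to zero mean and unit
#' variance using training-fold statistics only (leak-free). Setting
#' `paper_exact = TRUE` standardizes each timepoint/channel across all
#' epochs before cross-validation instead, replicating the common
#' toolbox convention of scaling before the CV split.
#'
#' @param ds A binary [eeg_epochs] (labels `"0"`/`"1"`, balanced).
#' @param n_folds Number of stratified CV folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param lambda L2 penalty on the sum-of-log-losses scale (the equivalent
#'   of an inverse regularization strength C = 1; default 1).
#' @param paper_exact Standardize globally across epochs before CV.
#' @param comparison_name Optional comparison label carried into the result.
#' @return A `decoding_timeseries`: list with `subject_id`, `comparison`,
#'   `accuracy` (per-timepoint fold-mean, in `[0,1]`), `time_ms`, `n_folds`.
#' @export
decode_timecourse <- function(ds, n_folds = 10, seed = 1L, lambda = 1,
                              paper_exact = FALSE,
                              comparison_name = NA_character_) {
  y <- binary_labels(ds)
  fold <- with_seed(derive_seed(seed, "folds"), stratified_folds(y, n_folds))
  acc <- .decode_timecourse_core(ds$data, y, as.integer(fold), lambda,
                                 paper_exact)
  structure(
    list(
      subject_id = ds$subject_id,
      comparison = comparison_name,
      accuracy = as.numeric(acc),
      time_ms = epoch_times(ds, "ms"),
      n_folds = as.integer(n_folds)
    ),
    class = "decoding_timeseries"
  )
}

binary_labels <- function(ds) {
  stopifnot(inherits(ds, "eeg_epochs"))
  if (!all(ds$stimulus_id %in% c("0", "1"))) {
    stop("expected a binarized dataset (labels '0'/'1'); run binarize() first")
  }
  as.numeric(ds$stimulus_id)
}

#' @export
print.decoding_timeseries <- function(x, ...) {
  cat("<decoding_timeseries>", x$subject_id,
      if (!is.na(x$comparison)) paste0("(", x$comparison, ")"), "\n")
  cat(sprintf("  %d timepoints, %d folds; mean accuracy %.3f, max %.3f at %.0f ms\n",
              length(x$accuracy), x$n_folds, mean(x$accuracy),
              max(x$accuracy), x$time_ms[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
plot.decoding_timeseries <- function(x, ...) {
  plot(x$time_ms, x$accuracy, type = "l", xlab = "time (ms)",
       ylab = "decoding accuracy", ylim = range(c(0.4, 0.6, x$accuracy)), ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Haufe activation patterns of the time-resolved decoder
#'
#' Linear classifier weights are not interpretable as neural sources; the
#' activation pattern A_t = Sigma_t w_t (feature covariance times weights)
#' is. For each timepoint the classifier is refit on all trials
#' (standardized across epochs), and its weight vector is multiplied by the
#' covariance of the raw (microvolt) channel features at that timepoint.
#'
#' @param ds A binary [eeg_epochs].
#' @param lambda L2 penalty (as in [decode_timecourse()]).
#' @return A `feature_importance_map`: list with `pattern` (channels x
#'   timepoints matrix, uV), `channel_names`, `time_ms`, `level =
#'   "subject"`.
#' @export
haufe_patterns <- function(ds, lambda = 1) {
  y <- binary_labels(ds)
  d <- dim(ds$data)
  pattern <- matrix(0, d[2L], d[3L],
                    dimnames = list(ds$channel_names, NULL))
  for (t in seq_len(d[3L])) {
    Xt <- ds$data[, , t]
    mu <- colMeans(Xt)
    sdv <- apply(Xt, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    Xs <- sweep(sweep(Xt, 2, mu), 2, sdv, "/")
    fit <- .ridge_logit_fit(Xs, y, lambda)
    w_std <- fit$w / sdv          # weights on the raw microvolt scale
    pattern[, t] <- stats::cov(Xt) %*% w_std
  }
  structure(
    list(pattern = pattern, channel_names = ds$channel_names,
         time_ms = epoch_times(ds, "ms"), level = "subject"),
    class = "feature_importance_map"
  )
}

#' Average activation patterns across subjects
#'
#' @param maps List of `feature_importance_map`s sharing montage and times.
#' @return A `feature_importance_map` with `level = "group"`.
#' @export
group_mean_patterns <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (!identical(m$channel_names, ref$channel_names) ||
        !isTRUE(all.equal(m$time_ms, ref$time_ms))) {
      stop("pattern maps do not share montage/time axis")
    }
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "pattern")) / length(maps)
  structure(
    list(pattern = avg, channel_names = ref$channel_names,
         time_ms = ref$time_ms, level = "group"),
    class = "feature_importance_map"
  )
}

#' @export
print.feature_importance_map <- function(x, ...) {
  cat("<feature_importance_map>", x$level, "level\n")
  peak <- which(abs(x$pattern) == max(abs(x$pattern)), arr.ind = TRUE)[1, ]
  cat(sprintf("  %d channels x %d timepoints; peak |A| = %.2f uV at %s, %.0f ms\n",
              nrow(x$pattern), ncol(x$pattern), max(abs(x$pattern)),
              x$channel_names[peak[1]], x$time_ms[peak[2]]))
  invisible(x)
}

#' Group mean and SEM of decoding time series
#'
#' @param series List of `decoding_timeseries` sharing a time axis.
#' @return A list with `time_ms`, `mean`, `sem` (sd/sqrt(n)), `n_subjects`,
#'   and the subject x time accuracy matrix `accuracy`.
#' @export
group_mean_sem <- function(series) {
  if (length(series) < 2) {
    stop("need at least 2 subjects for a group SEM")
  }
  ref <- series[[1L]]$time_ms
  for (s in series[-1L]) {
    if (!isTRUE(all.equal(s$time_ms, ref))) {
      stop("decoding time series do not share a time axis")
    }
  }
  A <- do.call(rbind, lapply(series, `[[`, "accuracy"))
  rownames(A) <- vapply(series, `[[`, "", "subject_id")
  structure(
    list(
      time_ms = ref,
      mean = colMeans(A),
      sem = apply(A, 2, stats::sd) / sqrt(nrow(A)),
      n_subjects = nrow(A),
      accuracy = A
    ),
    class = "group_accuracy"
  )
}

#' @export
print.group_accuracy <- function(x, ...) {
  cat("<group_accuracy>", x$n_subjects, "subjects,",
      length(x$time_ms), "timepoints\n")
  cat(sprintf("  grand mean accuracy %.3f; peak %.3f at %.0f ms\n",
              mean(x$mean), max(x$mean), x$time_ms[which.max(x$mean)]))
  invisible(x)
}

#' @export
plot.group_accuracy <- function(x, ...) {
  plot(x$time_ms, x$mean, type = "n", xlab = "time (ms)",
       ylab = "decoding accuracy",
       ylim = range(c(0.45, 0.6, x$mean + x$sem, x$mean - x$sem)), ...)
  graphics::polygon(c(x$time_ms, rev(x$time_ms)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    col = "grey85", border = NA)
  graphics::lines(x$time_ms, x$mean)
  graphics::abline(h = 0.5, lty = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
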