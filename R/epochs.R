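#' Epoched multichannel EEG for one subject
#'
#' The pipeline currency: a trials x channels x timepoints voltage array in
#' microvolts together with per-trial stimulus and session labels. All
#' downstream stages (preprocessing, decoding, inference) consume and return
#' this container.
#'
#' @param data Numeric array `[n_trials, n_channels, n_times]`, voltages in uV.
#' @param stimulus_id Character vector, one label per trial. For raw cohorts
#'   the vocabulary is `"human1"`, `"human2"`, `"monkey1"`, `"monkey2"`;
#'   after [binarize()] labels are `"0"`/`"1"`.
#' @param session_id Integer vector, one session index per trial (1 or 2).
#' @param subject_id Character scalar identifying the subject.
#' @param channel_names Character vector of unique channel labels, in the
#'   order of the second array dimension.
#' @param sfreq Sampling frequency in Hz.
#' @param tmin Epoch start relative to stimulus onset, in seconds (negative
#'   for a pre-stimulus baseline).
#'
#' @return An object of class `eeg_epochs`.
#' @seealso [generate_subject_epochs()], [baseline_correct()], [binarize()]
#' @export
eeg_epochs <- function(data, stimulus_id, session_id, subject_id,
                       channel_names, sfreq, tmin) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) {
    stop("epoch data contains non-finite values")
  }
  if (anyDuplicated(channel_names)) {
    stop("channel_names must be unique")
  }
  if (dim(data)[2L] != length(channel_names)) {
    stop("channel dimension (", dim(data)[2L], ") does not match ",
         length(channel_names), " channel names")
  }
  stimulus_id <- as.character(stimulus_id)
  session_id <- as.integer(session_id)
  if (length(stimulus_id) != dim(data)[1L] || length(session_id) != dim(data)[1L]) {
    stop("per-trial labels must match the number of trials")
  }
  if (anyNA(stimulus_id) || any(!nzchar(stimulus_id))) {
    stop("every trial needs a valid stimulus_id")
  }
  structure(
    list(
      data = data,
      stimulus_id = stimulus_id,
      session_id = session_id,
      subject_id = as.character(subject_id),
      channel_names = as.character(channel_names),
      sfreq = as.numeric(sfreq),
      tmin = as.numeric(tmin)
    ),
    class = "eeg_epochs"
  )
}

#' Number of trials, channels and timepoints of an epochs object
#' @param x An `eeg_epochs` object.
#' @return Integer vector `c(n_trials, n_channels, n_times)`.
#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Epoch time axis
#' @param x An `eeg_epochs` object.
#' @param unit `"s"` or `"ms"`.
#' @return Numeric vector of timepoints relative to stimulus onset.
#' @export
epoch_times <- function(x, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  tt <- x$tmin + (seq_len(dim(x$data)[3L]) - 1) / x$sfreq
  if (unit == "ms") tt * 1000 else tt
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> subject", x$subject_id, "\n")
  cat(sprintf("  %d trials x %d channels x %d timepoints (%.0f Hz, %.0f..%.0f ms)\n",
              d[1L], d[2L], d[3L], x$sfreq, x$tmin * 1000,
              (x$tmin + (d[3L] - 1) / x$sfreq) * 1000))
  tab <- table(x$stimulus_id)
  cat("  trials per stimulus:",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n")
  cat("  sessions:", paste(sort(unique(x$session_id)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset trials of an epochs object
#'
#' @param x An `eeg_epochs` object.
#' @param idx Integer or logical index over trials.
#' @return An `eeg_epochs` with the selected trials, order preserved.
#' @export
subset_trials <- function(x, idx) {
  eeg_epochs(
    data = x$data[idx, , , drop = FALSE],
    stimulus_id = x$stimulus_id[idx],
    session_id = x$session_id[idx],
    subject_id = x$subject_id,
    channel_names = x$channel_names,
    sfreq = x$sfreq,
    tmin = x$tmin
  )
}
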