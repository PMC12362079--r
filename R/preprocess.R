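#' Binary comparisons of the face experiment
#'
#' Each comparison maps the four stimulus labels onto two classes:
#' `face_categorization` contrasts both human identities against both monkey
#' identities; `human_individuation` contrasts the two human identities
#' (monkey trials dropped); `monkey_individuation` analogously.
#'
#' @param name One of `"face_categorization"`, `"human_individuation"`,
#'   `"monkey_individuation"`.
#' @return A `comparison` list with `name` and `class_map` (named vector
#'   stimulus label -> 0/1).
#' @export
comparison <- function(name = c("face_categorization",
                                "human_individuation",
                                "monkey_individuation")) {
  name <- match.arg(name)
  class_map <- switch(
    name,
    face_categorization = c(human1 = 0, human2 = 0, monkey1 = 1, monkey2 = 1),
    human_individuation = c(human1 = 0, human2 = 1),
    monkey_individuation = c(monkey1 = 0, monkey2 = 1)
  )
  structure(list(name = name, class_map = class_map), class = "comparison")
}

#' All three standard comparisons
#' @return Character vector of comparison names.
#' @export
comparison_names <- function() {
  c("face_categorization", "human_individuation", "monkey_individuation")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the 200 ms
#' pre-stimulus window `[-200, 0)` ms from the whole epoch. Idempotent.
#'
#' @param ds An [eeg_epochs] object with `tmin <= -0.2`.
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(ds) {
  stopifnot(inherits(ds, "eeg_epochs"))
  if (ds$tmin > -0.2 + 1e-9) {
    stop("epoch lacks a 200 ms pre-stimulus baseline (tmin = ", ds$tmin, " s)")
  }
  tt <- epoch_times(ds, "ms")
  bidx <- which(tt >= -200 & tt < 0)
  if (!length(bidx)) stop("epoch lacks pre-stimulus samples")
  d <- ds$data
  # per-trial, per-channel baseline mean: [trials, channels]
  bmean <- apply(d[, , bidx, drop = FALSE], c(1, 2), mean)
  ds$data <- d - array(bmean, dim = dim(d))
  ds
}

#' Balance trial counts across the four stimuli
#'
#' Randomly removes surplus trials from the majority classes until all four
#' stimulus labels have the minimum class count. Removal is uniform given
#' `seed`; the relative order of retained trials is preserved. Intended to
#' run per session, before [concatenate_sessions()].
#'
#' @param ds An [eeg_epochs] with all four stimulus labels present.
#' @param seed Integer seed for the random down-sampling.
#' @return A balanced `eeg_epochs`.
#' @export
balance_trials <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "eeg_epochs"))
  counts <- table(factor(ds$stimulus_id, levels = stimulus_levels()))
  missing <- names(counts)[counts == 0]
  if (length(missing)) {
    stop("stimulus absent from the data: ", paste(missing, collapse = ", "))
  }
  target <- min(counts)
  if (all(counts == target)) return(ds)
  keep <- with_seed(derive_seed(seed, "balance"), {
    unlist(lapply(stimulus_levels(), function(s) {
      idx <- which(ds$stimulus_id == s)
      if (length(idx) > target) sort(sample(idx, target)) else idx
    }))
  })
  subset_trials(ds, sort(keep))
}

#' Concatenate balanced sessions of one subject
#'
#' Stacks per-session epochs along the trial dimension after checking that
#' all metadata agree. Balancing must be done per session beforehand so the
#' session identity cannot be decoded through class imbalance.
#'
#' @param ds_list List of [eeg_epochs] sharing subject, montage, sfreq,
#'   tmin and n_times.
#' @return A single concatenated `eeg_epochs`.
#' @export
concatenate_sessions <- function(ds_list) {
  stopifnot(length(ds_list) >= 1, all(vapply(ds_list, inherits, TRUE, "eeg_epochs")))
  if (length(ds_list) == 1L) return(ds_list[[1L]])
  ref <- ds_list[[1L]]
  for (ds in ds_list[-1L]) {
    for (field in c("subject_id", "channel_names", "sfreq", "tmin")) {
      if (!identical(ds[[field]], ref[[field]])) {
        stop("session metadata mismatch in field: ", field)
      }
    }
    if (dim(ds$data)[3L] != dim(ref$data)[3L]) {
      stop("session metadata mismatch in field: n_times")
    }
  }
  n_tr <- vapply(ds_list, function(d) dim(d$data)[1L], 1L)
  d <- array(0, dim = c(sum(n_tr), dim(ref$data)[2L], dim(ref$data)[3L]))
  off <- 0L
  for (ds in ds_list) {
    d[off + seq_len(dim(ds$data)[1L]), , ] <- ds$data
    off <- off + dim(ds$data)[1L]
  }
  eeg_epochs(
    data = d,
    stimulus_id = unlist(lapply(ds_list, `[[`, "stimulus_id")),
    session_id = unlist(lapply(ds_list, `[[`, "session_id")),
    subject_id = ref$subject_id,
    channel_names = ref$channel_names,
    sfreq = ref$sfreq,
    tmin = ref$tmin
  )
}

#' Relabel epochs for one binary comparison
#'
#' Drops trials not covered by the comparison's class map and relabels the
#' rest as `"0"`/`"1"`. With balanced input the two classes stay balanced.
#'
#' @param ds An [eeg_epochs] with stimulus labels.
#' @param comp A [comparison()].
#' @return An `eeg_epochs` whose `stimulus_id` is `"0"`/`"1"`.
#' @export
binarize <- function(ds, comp) {
  stopifnot(inherits(ds, "eeg_epochs"), inherits(comp, "comparison"))
  cls <- comp$class_map[ds$stimulus_id]
  keep <- which(!is.na(cls))
  y <- cls[keep]
  if (length(unique(y)) < 2L) {
    stop("comparison '", comp$name, "' leaves an empty class")
  }
  out <- subset_trials(ds, keep)
  out$stimulus_id <- as.character(y)
  out
}

#' Participant inclusion rule on trial counts
#'
#' A subject is included if every stimulus category exceeds 20 trials in
#' each of two sessions, or exceeds 35 trials in a single session.
#' Inequalities are strict.
#'
#' @param trial_counts Numeric matrix `[n_sessions, n_categories]` (or a
#'   vector for a single session) of available trials.
#' @return `TRUE` if the subject passes, else `FALSE`.
#' @export
check_inclusion <- function(trial_counts) {
  m <- if (is.matrix(trial_counts)) trial_counts else
    matrix(trial_counts, nrow = 1)
  stopifnot(all(m >= 0))
  if (nrow(m) >= 2) {
    all(m > 20)
  } else {
    all(m > 35)
  }
}

#' Standard per-subject preparation
#'
#' Convenience wrapper running the session-wise steps in order: optional
#' baseline correction, per-session balancing, session concatenation.
#'
#' @param ds An [eeg_epochs] (possibly spanning two sessions).
#' @param seed Seed for the balancing down-sampling.
#' @param baseline Apply [baseline_correct()] first (default `TRUE`).
#' @return A balanced, concatenated `eeg_epochs`.
#' @export
preprocess_subject <- function(ds, seed = 1L, baseline = TRUE) {
  stopifnot(inherits(ds, "eeg_epochs"))
  if (baseline) ds <- baseline_correct(ds)
  sessions <- sort(unique(ds$session_id))
  parts <- lapply(seq_along(sessions), function(i) {
    balance_trials(subset_trials(ds, ds$session_id == sessions[i]),
                   seed = derive_seed(seed, "session", i))
  })
  concatenate_sessions(parts)
}
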