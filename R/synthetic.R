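#' Configuration for a synthetic infant-EEG cohort
#'
#' Defines the geometry and statistical structure of a simulated
#' event-related face experiment: four stimuli (two human and two monkey
#' identities), 31-channel epochs sampled at `sfreq` from `tmin` to `tmax`
#' seconds around stimulus onset, a species-contrast pattern injected over
#' occipito-parietal channels inside `effect_window`, optional (default
#' absent) identity contrasts, an evoked class-independent background, and
#' temporally autocorrelated 1/f-like noise.
#'
#' Signal amplitudes are in microvolts. `species_effect_uv` is added with
#' opposite sign for human versus monkey trials on `effect_channels`;
#' `identity_effect_uv` analogously separates the two identities within each
#' species. `prevalence_true` controls the fraction of subjects that carry
#' the species effect at all, enabling prevalence-recovery simulations: the
#' first `round(n_subjects * prevalence_true)` subjects are carriers.
#'
#' The default amplitude regime (`species_effect_uv = 1.65`,
#' `noise_sd_uv = 10`, per-subject lognormal amplitude spread
#' `subject_effect_sd = 0.4`) is calibrated so that roughly half the
#' simulated subjects reach individual significance in full-trial decoding,
#' the regime the package's recovery simulations target.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_trials_per_stimulus Trials per stimulus label per session
#'   (minimum 10, so stratified 10-fold CV is supported).
#' @param n_sessions 1 or 2 recording sessions.
#' @param channels Ordered channel labels (default: the 31-channel infant
#'   montage used throughout the package).
#' @param sfreq Sampling frequency in Hz.
#' @param tmin,tmax Epoch limits in seconds around stimulus onset.
#' @param effect_window Start and end of the injected effect, in ms.
#' @param effect_channels Channel labels carrying the effect.
#' @param species_effect_uv Amplitude of the human-vs-monkey pattern, uV.
#' @param identity_effect_uv Amplitude of the within-species identity
#'   pattern, uV (default 0: no individuation signal).
#' @param noise_sd_uv Per-sample noise standard deviation, uV.
#' @param subject_effect_sd Lognormal sd of the per-subject effect-amplitude
#'   multiplier (0 = homogeneous subjects).
#' @param prevalence_true Fraction of subjects carrying the species effect.
#' @param seed Master seed; each subject draws from a derived sub-stream.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20,
                          n_trials_per_stimulus = 40,
                          n_sessions = 2,
                          channels = eegmvpa_montage(),
                          sfreq = 250,
                          tmin = -0.2,
                          tmax = 1.0,
                          effect_window = c(200, 770),
                          effect_channels = c("O1", "O2", "Oz", "POz",
                                              "P7", "P8", "P3", "P4"),
                          species_effect_uv = 1.65,
                          identity_effect_uv = 0,
                          noise_sd_uv = 10,
                          subject_effect_sd = 0.4,
                          prevalence_true = 1.0,
                          seed = 1L) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
      n_sessions = as.integer(n_sessions),
      channels = as.character(channels),
      sfreq = as.numeric(sfreq),
      tmin = as.numeric(tmin),
      tmax = as.numeric(tmax),
      effect_window = as.numeric(effect_window),
      effect_channels = as.character(effect_channels),
      species_effect_uv = as.numeric(species_effect_uv),
      identity_effect_uv = as.numeric(identity_effect_uv),
      noise_sd_uv = as.numeric(noise_sd_uv),
      subject_effect_sd = as.numeric(subject_effect_sd),
      prevalence_true = as.numeric(prevalence_true),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' The default 31-channel infant EEG montage
#'
#' Channel labels of the recording montage assumed by the synthetic
#' generator (31 scalp electrodes of a 34-electrode active-electrode cap,
#' EOG/reference/ground excluded).
#'
#' @return Character vector of 31 channel labels.
#' @export
eegmvpa_montage <- function() {
  c("Fz", "F3", "F7", "F9", "FC5", "POz", "C3", "T7", "TP9", "CP5",
    "P7", "P3", "Pz", "O1", "O2", "P8", "P4", "CP6", "TP10", "T8",
    "C4", "Oz", "FC6", "F10", "F8", "F4", "Fp2", "FC4", "CP4", "FC3", "CP3")
}

validate_cohort_config <- function(cfg) {
  if (!(cfg$tmin < 0 && 0 < cfg$tmax)) {
    stop("configuration error: need tmin < 0 < tmax")
  }
  if (cfg$effect_window[1] < 0 || cfg$effect_window[2] > cfg$tmax * 1000 ||
      cfg$effect_window[1] >= cfg$effect_window[2]) {
    stop("configuration error: effect_window must lie within [0, tmax] (ms)")
  }
  if (cfg$n_trials_per_stimulus < 10) {
    stop("configuration error: n_trials_per_stimulus must be >= 10")
  }
  if (!(cfg$n_sessions %in% c(1L, 2L))) {
    stop("configuration error: n_sessions must be 1 or 2")
  }
  if (cfg$prevalence_true < 0 || cfg$prevalence_true > 1) {
    stop("configuration error: prevalence_true must be in [0, 1]")
  }
  if (cfg$species_effect_uv < 0 || cfg$identity_effect_uv < 0 ||
      cfg$noise_sd_uv < 0) {
    stop("configuration error: amplitudes must be >= 0")
  }
  unknown <- setdiff(cfg$effect_channels, cfg$channels)
  if (length(unknown)) {
    stop("configuration error: unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(cfg$channels)) {
    stop("configuration error: duplicate channel labels")
  }
  invisible(cfg)
}

stimulus_levels <- function() c("human1", "human2", "monkey1", "monkey2")

# Plateau envelope over the effect window: half-cosine ramps (15% of the
# window each side) around a flat top, sampled on the epoch time axis.
effect_envelope <- function(times_ms, window, ramp_frac = 0.15) {
  env <- numeric(length(times_ms))
  w0 <- window[1]; w1 <- window[2]
  ramp <- (w1 - w0) * ramp_frac
  inside <- times_ms >= w0 & times_ms <= w1
  tt <- times_ms[inside]
  e <- rep(1, length(tt))
  up <- tt < w0 + ramp
  e[up] <- 0.5 * (1 - cos(pi * (tt[up] - w0) / ramp))
  dn <- tt > w1 - ramp
  e[dn] <- 0.5 * (1 - cos(pi * (w1 - tt[dn]) / ramp))
  env[inside] <- e
  env
}

# Spatial gain of the injected pattern: full weight on occipital leads,
# weaker on the surrounding parietal/posterior-temporal leads.
effect_channel_gain <- function(channels, effect_channels) {
  gain <- numeric(length(channels))
  occ <- c("O1", "O2", "Oz", "POz")
  idx <- match(effect_channels, channels)
  gain[idx] <- ifelse(effect_channels %in% occ, 1.0, 0.6)
  gain
}

# Class-independent evoked waveform (uV): early positivity, a mid-latency
# negativity and a slow late wave, zero before stimulus onset.
evoked_waveform <- function(times_s) {
  w <- 5 * exp(-(times_s - 0.10)^2 / (2 * 0.03^2)) -
    6 * exp(-(times_s - 0.29)^2 / (2 * 0.05^2)) +
    4 * exp(-(times_s - 0.55)^2 / (2 * 0.15^2))
  w[times_s < 0] <- 0
  w
}

# 1/f-like noise for one subject: per trial and channel, a sum of eight
# sinusoids with 1/f amplitudes and random phases plus white noise; a
# shared per-trial component induces cross-channel correlation ~0.3.
# Returns an array [n_trials, n_channels, n_times] with unit sd, to be
# scaled by noise_sd_uv.
pink_noise_array <- function(n_trials, n_channels, times_s, rho = 0.3) {
  freqs <- c(1, 2, 3, 5, 8, 13, 21, 34)
  amp <- 1 / freqs
  sin_var_target <- 0.7                       # fraction of variance from sinusoids
  amp <- amp * sqrt(sin_var_target / sum(amp^2 / 2))
  white_sd <- sqrt(1 - sin_var_target)

  n_times <- length(times_s)
  n_units <- n_trials * (n_channels + 1L)     # +1: shared component per trial
  # sin(w t + phi) = sin(phi) cos(w t) + cos(phi) sin(w t): one BLAS product
  phi <- matrix(stats::runif(n_units * length(freqs), 0, 2 * pi),
                n_units, length(freqs))
  A <- cbind(sin(phi) %*% diag(amp), cos(phi) %*% diag(amp))
  B <- rbind(t(sapply(freqs, function(f) cos(2 * pi * f * times_s))),
             t(sapply(freqs, function(f) sin(2 * pi * f * times_s))))
  S <- A %*% B
  S <- S + matrix(stats::rnorm(n_units * n_times, sd = white_sd),
                  n_units, n_times)

  shared <- S[seq_len(n_trials), , drop = FALSE]
  private <- S[-seq_len(n_trials), , drop = FALSE]
  out <- array(0, dim = c(n_trials, n_channels, n_times))
  sq_r <- sqrt(rho); sq_p <- sqrt(1 - rho)
  for (ch in seq_len(n_channels)) {
    rows <- (ch - 1L) * n_trials + seq_len(n_trials)
    out[, ch, ] <- sq_p * private[rows, , drop = FALSE] + sq_r * shared
  }
  out
}

#' Generate one subject's synthetic epochs
#'
#' Builds an [eeg_epochs] object as the sum of an evoked class-independent
#' background, a species-contrast pattern (opposite sign for human vs monkey
#' trials on the effect channels inside the effect window, present only if
#' the subject is an effect carrier), an analogous identity-contrast
#' pattern, and 1/f-like autocorrelated noise. Per-trial effect amplitudes
#' carry multiplicative lognormal jitter (sd 0.2); per-subject amplitudes a
#' lognormal factor with sd `cfg$subject_effect_sd`.
#'
#' Deterministic given `(cfg$seed, subject_index)`.
#'
#' @param cfg A [cohort_config()].
#' @param subject_index 1-based subject index (`<= cfg$n_subjects`).
#' @return A list with elements `epochs` (an `eeg_epochs`) and
#'   `ground_truth` (carrier flags and the injected channels x timepoints
#'   species pattern in uV).
#' @export
generate_subject_epochs <- function(cfg, subject_index) {
  validate_cohort_config(cfg)
  stopifnot(subject_index >= 1, subject_index <= cfg$n_subjects)

  n_times <- round((cfg$tmax - cfg$tmin) * cfg$sfreq) + 1L
  times_s <- cfg$tmin + (seq_len(n_times) - 1) / cfg$sfreq
  times_ms <- times_s * 1000
  n_ch <- length(cfg$channels)
  n_carriers <- round(cfg$n_subjects * cfg$prevalence_true)
  has_species <- subject_index <= n_carriers
  has_identity <- cfg$identity_effect_uv > 0

  per_session <- cfg$n_trials_per_stimulus
  stim_session <- rep(stimulus_levels(), each = per_session)
  stimulus_id <- rep(stim_session, times = cfg$n_sessions)
  session_id <- rep(seq_len(cfg$n_sessions), each = length(stim_session))
  n_trials <- length(stimulus_id)

  env <- effect_envelope(times_ms, cfg$effect_window)
  gain <- effect_channel_gain(cfg$channels, cfg$effect_channels)
  base_pattern <- outer(gain, env)            # channels x times, unit amplitude

  with_seed(derive_seed(cfg$seed, "subject", subject_index), {
    subj_amp <- stats::rlnorm(1, 0, cfg$subject_effect_sd)
    chan_gain_bg <- stats::runif(n_ch, 0.5, 1.5)
    noise <- pink_noise_array(n_trials, n_ch, times_s) * cfg$noise_sd_uv
    trial_jitter <- stats::rlnorm(n_trials, 0, 0.2)

    species_sign <- ifelse(grepl("^human", stimulus_id), 1, -1)
    identity_sign <- ifelse(grepl("1$", stimulus_id), 1, -1)

    species_pattern <- if (has_species) {
      cfg$species_effect_uv * subj_amp * base_pattern
    } else {
      base_pattern * 0
    }
    identity_pattern <- if (has_identity) {
      cfg$identity_effect_uv * subj_amp * base_pattern
    } else {
      base_pattern * 0
    }

    data <- noise
    bg <- outer(chan_gain_bg, evoked_waveform(times_s))  # channels x times
    for (tr in seq_len(n_trials)) {
      data[tr, , ] <- data[tr, , ] + bg +
        trial_jitter[tr] * (species_sign[tr] * species_pattern +
                              identity_sign[tr] * identity_pattern)
    }

    list(
      epochs = eeg_epochs(
        data = data,
        stimulus_id = stimulus_id,
        session_id = session_id,
        subject_id = sprintf("sub-%02d", subject_index),
        channel_names = cfg$channels,
        sfreq = cfg$sfreq,
        tmin = cfg$tmin
      ),
      ground_truth = list(
        subject_id = sprintf("sub-%02d", subject_index),
        has_species_effect = has_species,
        has_identity_effect = has_identity,
        species_pattern = species_pattern,
        identity_pattern = identity_pattern
      )
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Calls [generate_subject_epochs()] for every subject. Exactly
#' `round(n_subjects * prevalence_true)` subjects (the first ones by index)
#' carry the species effect; the carrier flags are returned as ground truth
#' so recovery simulations can score themselves.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `subjects` (list of `eeg_epochs`) and `ground_truth`
#'   (per-subject flags and injected patterns).
#' @export
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  out <- lapply(seq_len(cfg$n_subjects), function(i) {
    generate_subject_epochs(cfg, i)
  })
  list(
    subjects = lapply(out, `[[`, "epochs"),
    ground_truth = lapply(out, `[[`, "ground_truth")
  )
}
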