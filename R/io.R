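#' Write one subject's epochs to the on-disk container
#'
#' A subject is stored as two files in `dir`: `<subject_id>.dat`, the
#' voltage array as little-endian float32 in trial-major order (trials x
#' channels x timepoints, column-major as in R), and `<subject_id>.json`,
#' a key-value sidecar holding the shape and metadata (subject id, channel
#' names in order, sfreq, tmin, per-trial stimulus and session labels).
#' Voltages are truncated to float32 on write; writing is idempotent after
#' one write-read round trip.
#'
#' @param ds An [eeg_epochs] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_epochs <- function(ds, dir) {
  stopifnot(inherits(ds, "eeg_epochs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dat_path <- file.path(dir, paste0(ds$subject_id, ".dat"))
  meta_path <- file.path(dir, paste0(ds$subject_id, ".json"))
  con <- file(dat_path, "wb")
  writeBin(as.numeric(ds$data), con, size = 4L, endian = "little")
  close(con)
  meta <- list(
    subject_id = ds$subject_id,
    shape = dim(ds$data),
    channel_names = ds$channel_names,
    sfreq = ds$sfreq,
    tmin = ds$tmin,
    stimulus_id = ds$stimulus_id,
    session_id = ds$session_id
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(dat_path, meta_path))
}

#' Read one subject's epochs from the on-disk container
#'
#' @param dir Container directory.
#' @param subject_id Subject whose files to read.
#' @return An [eeg_epochs] object.
#' @export
read_epochs <- function(dir, subject_id) {
  dat_path <- file.path(dir, paste0(subject_id, ".dat"))
  meta_path <- file.path(dir, paste0(subject_id, ".json"))
  if (!file.exists(dat_path) || !file.exists(meta_path)) {
    stop("no container files for subject '", subject_id, "' in ", dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(dat_path, "rb")
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  close(con)
  if (length(vals) != n) {
    stop("container data for '", subject_id, "' truncated: expected ", n,
         " values, got ", length(vals))
  }
  eeg_epochs(
    data = array(vals, dim = shape),
    stimulus_id = meta$stimulus_id,
    session_id = meta$session_id,
    subject_id = meta$subject_id,
    channel_names = meta$channel_names,
    sfreq = meta$sfreq,
    tmin = meta$tmin
  )
}

#' List subjects present in a container directory
#' @param dir Container directory.
#' @return Character vector of subject ids (sorted).
#' @export
list_container_subjects <- function(dir) {
  metas <- list.files(dir, pattern = "\\.json$")
  sort(sub("\\.json$", "", metas))
}

#' Write a cohort to a container directory
#' @param subjects List of [eeg_epochs] objects.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(subjects, dir) {
  for (ds in subjects) write_epochs(ds, dir)
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
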