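#' Trial-aligned multichannel recordings
#'
#' A `trial_set` holds trial-aligned neural recordings as a numeric array of
#' dimension `n_trials x n_channels x n_samples`, together with the sampling
#' rate, one condition label per trial and one identifier per channel. All
#' trials must have the same length and the data must be finite. Amplitude
#' units are not interpreted: the decoding method is covariant under
#' per-channel rescaling.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`. A matrix is
#'   accepted for a single trial and promoted to a 1-trial array.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of per-trial condition labels (e.g. finger
#'   or word names). Defaults to a single condition `"cond1"`.
#' @param channel_ids character vector of channel names. Defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @return An object of class `trial_set`.
#' @seealso [target_set()], [epoch()], [read_trialset()]
#' @export
trial_set <- function(data, fs, labels = NULL, channel_ids = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be an array [n_trials, n_channels, n_samples]")
  }
  d <- dim(data)
  if (is.null(labels)) labels <- rep("cond1", d[1L])
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(d[2L]))
  obj <- structure(
    list(data = data, fs = as.numeric(fs),
         labels = as.character(labels),
         channel_ids = as.character(channel_ids)),
    class = "trial_set")
  validate_trial_set(obj)
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  tab <- table(x$labels)
  cat("conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

validate_trial_set <- function(x) {
  d <- dim(x$data)
  if (d[1L] < 1L) stop("trial_set must contain at least one trial")
  if (!is.numeric(x$fs) || length(x$fs) != 1L || !is.finite(x$fs) || x$fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (length(x$labels) != d[1L]) {
    stop(sprintf("label/trial count mismatch: %d labels for %d trials",
                 length(x$labels), d[1L]))
  }
  if (length(x$channel_ids) != d[2L]) {
    stop(sprintf("channel_ids length %d does not match %d channels",
                 length(x$channel_ids), d[2L]))
  }
  bad <- which(!apply(x$data, 1L, function(tr) all(is.finite(tr))))
  if (length(bad)) {
    stop(sprintf("non-finite values in trial %d", bad[1L]))
  }
  x
}

#' Per-trial target signals
#'
#' A `target_set` holds one target trace per trial (finger position, speech
#' amplitude envelope, or a synthetic target) as a numeric matrix
#' `n_trials x n_samples` at a common sampling rate.
#'
#' @param data numeric matrix `[n_trials, n_samples]`; a vector is promoted
#'   to a single-trial matrix.
#' @param fs sampling rate in Hz.
#' @param modality one of `"glove"`, `"envelope"`, `"synthetic"`.
#' @return An object of class `target_set`.
#' @export
target_set <- function(data, fs, modality = c("synthetic", "glove", "envelope")) {
  modality <- match.arg(modality)
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data)) stop("`data` must be a matrix [n_trials, n_samples]")
  if (!all(is.finite(data))) stop("target data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  structure(list(data = data, fs = as.numeric(fs), modality = modality),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %d trials x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$modality))
  invisible(x)
}

n_trials <- function(x) {
  if (inherits(x, "trial_set") || inherits(x, "feature_tensor")) dim(x$data)[1L]
  else if (inherits(x, "target_set")) nrow(x$data)
  else stop("unsupported type")
}

n_samples <- function(x) {
  if (inherits(x, "trial_set") || inherits(x, "feature_tensor")) dim(x$data)[3L]
  else if (inherits(x, "target_set")) ncol(x$data)
  else stop("unsupported type")
}

#' Write a dataset container
#'
#' Serializes a [trial_set()] (optionally paired with a [target_set()]) into
#' a single self-describing file with three groups: `trials` (the tensor),
#' `targets` (the matrix, if any) and `meta` (sampling rates, labels, channel
#' identifiers). Round-trips are bit-exact.
#'
#' @param trials a `trial_set`.
#' @param path output file path.
#' @param targets optional paired `target_set` with the same number of trials.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trials, path, targets = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (!is.null(targets)) {
    stopifnot(inherits(targets, "target_set"))
    if (nrow(targets$data) != dim(trials$data)[1L]) {
      stop("targets and trials disagree on the number of trials")
    }
  }
  payload <- list(
    format = "cohdecode-container",
    version = 1L,
    trials = trials$data,
    targets = if (is.null(targets)) NULL else targets$data,
    meta = list(fs = trials$fs,
                target_fs = if (is.null(targets)) NULL else targets$fs,
                target_modality = if (is.null(targets)) NULL else targets$modality,
                labels = trials$labels,
                channel_ids = trials$channel_ids))
  saveRDS(payload, path)
  invisible(path)
}

#' Read a dataset container or a CSV-per-trial directory
#'
#' @param path a container file written by [write_trialset()], or (with
#'   `format = "csvdir"`) a directory of per-trial CSV files, each
#'   `samples x channels` with a header row of channel identifiers.
#' @param format `"container"` (single serialized file) or `"csvdir"`.
#' @param fs sampling rate in Hz; required for `"csvdir"` (the container
#'   stores its own).
#' @param labels optional per-trial labels for `"csvdir"` (one per file,
#'   files taken in lexicographic order).
#' @return A `trial_set`. For containers holding targets, the paired
#'   `target_set` is attached as attribute `"targets"`.
#' @export
read_trialset <- function(path, format = c("container", "csvdir"),
                          fs = NULL, labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "container") {
    payload <- readRDS(path)
    if (!identical(payload$format, "cohdecode-container")) {
      stop("not a cohdecode container file")
    }
    ts <- trial_set(payload$trials, fs = payload$meta$fs,
                    labels = payload$meta$labels,
                    channel_ids = payload$meta$channel_ids)
    if (!is.null(payload$targets)) {
      attr(ts, "targets") <- target_set(payload$targets,
                                        fs = payload$meta$target_fs,
                                        modality = payload$meta$target_modality)
    }
    return(ts)
  }
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no CSV files in directory: %s", path))
  if (is.null(fs)) stop("`fs` is required when reading a CSV directory")
  mats <- lapply(files, function(f) {
    as.matrix(utils::read.csv(f, check.names = FALSE))
  })
  lens <- vapply(mats, nrow, 0L)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged trial lengths: trial %d (%s) has %d samples, expected %d",
                 bad, basename(files[bad]), lens[bad], lens[1L]))
  }
  chans <- colnames(mats[[1L]])
  data <- array(0, dim = c(length(mats), ncol(mats[[1L]]), lens[1L]))
  for (k in seq_along(mats)) data[k, , ] <- t(mats[[k]])
  trial_set(data, fs = fs, labels = labels, channel_ids = chans)
}

#' Epoch a continuous recording into trials
#'
#' Cuts half-open windows `[onset, onset + round(duration * fs))` out of a
#' continuous multichannel recording. Onsets are 0-based sample indices, so
#' contiguous non-overlapping epochs concatenate back to the source segment
#' without duplicating or dropping any sample.
#'
#' @param continuous numeric matrix `[n_channels, n_total]`.
#' @param fs sampling rate in Hz.
#' @param onsets integer vector of 0-based onset sample indices.
#' @param duration epoch duration in seconds; the window length in samples is
#'   `round(duration * fs)`.
#' @param labels optional per-epoch labels.
#' @param channel_ids optional channel names.
#' @return A `trial_set` with `length(onsets)` trials.
#' @export
epoch <- function(continuous, fs, onsets, duration, labels = NULL,
                  channel_ids = NULL) {
  if (!is.matrix(continuous)) stop("`continuous` must be a matrix [n_channels, n_total]")
  len <- round(duration * fs)
  if (len < 1L) stop("empty window: duration must cover at least one sample")
  n_total <- ncol(continuous)
  onsets <- as.integer(onsets)
  if (any(onsets < 0L)) stop("onsets must be non-negative 0-based sample indices")
  over <- which(onsets + len > n_total)
  if (length(over)) {
    stop(sprintf("window exceeds the recording for onset %d (needs samples up to %d of %d)",
                 onsets[over[1L]], onsets[over[1L]] + len, n_total))
  }
  data <- array(0, dim = c(length(onsets), nrow(continuous), len))
  for (k in seq_along(onsets)) {
    data[k, , ] <- continuous[, (onsets[k] + 1L):(onsets[k] + len), drop = FALSE]
  }
  trial_set(data, fs = fs, labels = labels, channel_ids = channel_ids)
}
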