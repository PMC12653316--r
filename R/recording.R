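#' EEG recording container
#'
#' One subject-by-condition continuous multichannel signal in microvolts,
#' stored as a samples x channels matrix with its montage and sampling rate.
#'
#' @param signal Numeric matrix, samples x channels (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param montage A `channel_montage`; column count of `signal` must match.
#' @param subject_id Subject identifier.
#' @param condition `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @param trial_length Optional trial length in seconds when the signal is a
#'   concatenation of fixed-length trials; used by [extract_epochs()] to keep
#'   epochs from spanning trial boundaries.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, montage = default_montage(),
                          subject_id = "S000", condition = c("EO", "EC"),
                          trial_length = NULL) {
  condition <- match.arg(condition)
  signal <- as.matrix(signal)
  if (ncol(signal) != length(montage$labels))
    stop("signal has ", ncol(signal), " channels but montage has ",
         length(montage$labels))
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  colnames(signal) <- montage$labels
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 montage = montage, subject_id = subject_id,
                 condition = condition, trial_length = trial_length),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, ncol(x$signal), nrow(x$signal),
              x$sampling_rate, nrow(x$signal) / x$sampling_rate))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$signal)

#' Epoch container
#'
#' Fixed-length epochs cut from a recording, with a per-epoch retained flag.
#' Stored as a 3-d array epoch x sample x channel.
#'
#' @param epochs Numeric array, epoch x sample x channel.
#' @param epoch_length Epoch length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage The `channel_montage` of the source recording.
#' @param retained Logical vector, one flag per epoch.
#' @param subject_id,condition Provenance carried from the recording.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, epoch_length, sampling_rate,
                      montage = default_montage(),
                      retained = rep(TRUE, dim(epochs)[1]),
                      subject_id = "S000", condition = "EO") {
  stopifnot(length(dim(epochs)) == 3)
  expected <- round(epoch_length * sampling_rate)
  if (dim(epochs)[2] != expected)
    stop("epoch sample count (", dim(epochs)[2],
         ") must equal epoch_length * sampling_rate (", expected, ")")
  if (length(retained) != dim(epochs)[1])
    stop("retained flag length must equal epoch count")
  structure(list(epochs = epochs, epoch_length = epoch_length,
                 sampling_rate = sampling_rate, montage = montage,
                 retained = retained, subject_id = subject_id,
                 condition = condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s/%s: %d epochs x %g s (%d retained = %g s clean)\n",
    x$subject_id, x$condition, dim(x$epochs)[1], x$epoch_length,
    sum(x$retained), sum(x$retained) * x$epoch_length))
  invisible(x)
}

#' Retained clean duration of an epoch set, in seconds
#' @param es An `epoch_set`.
#' @export
retained_seconds <- function(es) sum(es$retained) * es$epoch_length
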