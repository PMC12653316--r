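#' Preprocessing configuration
#'
#' Parameters for the fixed preprocessing chain applied to every recording:
#' average re-reference, zero-phase bandpass, epoching, peak-to-peak artifact
#' rejection, and the minimum-clean-data retention rule.
#'
#' @param band_low,band_high Bandpass edges in Hz (default 0.5-100).
#' @param epoch_length Epoch length in seconds (default 4).
#' @param reject_ptp_threshold Peak-to-peak rejection threshold in microvolts
#'   (default 100): an epoch is rejected iff any channel's max-minus-min
#'   within the epoch exceeds this.
#' @param min_clean_seconds Minimum retained clean data per subject and
#'   condition (default 60 s); below it the subject x condition is excluded.
#' @param filter_order Butterworth order of the zero-phase bandpass (default 4).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.5, band_high = 100,
                              epoch_length = 4, reject_ptp_threshold = 100,
                              min_clean_seconds = 60, filter_order = 4) {
  if (band_low <= 0 || band_low >= band_high)
    stop("require 0 < band_low < band_high")
  if (min_clean_seconds < epoch_length)
    stop("min_clean_seconds must be >= epoch_length")
  structure(list(band_low = band_low, band_high = band_high,
                 epoch_length = epoch_length,
                 reject_ptp_threshold = reject_ptp_threshold,
                 min_clean_seconds = min_clean_seconds,
                 filter_order = filter_order),
            class = "preprocess_config")
}

#' Average re-reference
#'
#' Subtracts, at every sample, the instantaneous mean across all channels.
#' Linear and idempotent; removes any common-mode (shared) component.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$signal) < 2)
    stop("average reference requires at least 2 channels")
  labs <- colnames(rec$signal)
  rec$signal <- cpp_average_reference(rec$signal)
  colnames(rec$signal) <- labs
  rec
}

# Squared-magnitude response of an order-n Butterworth bandpass
# (highpass at `low` cascaded with lowpass at `high`), evaluated at
# frequencies f.  This is the exact gain a forward-backward (zero-phase)
# Butterworth application would have.
butterworth_gain2 <- function(f, low, high, order) {
  xh <- (f / low)^(2 * order)
  hp <- xh / (1 + xh)
  hp[f == 0] <- 0
  lp <- 1 / (1 + (f / high)^(2 * order))
  hp * lp
}

#' Zero-phase bandpass filter
#'
#' Applies a zero-phase bandpass with the squared-magnitude response of a
#' 4th-order Butterworth (highpass-lowpass cascade) in the frequency domain.
#' This is the response that forward-backward ("filtfilt") application of the
#' same Butterworth approximates, realised exactly and without phase
#' distortion.  Edge transients are controlled by reflective padding of at
#' least three filter time constants of the low cutoff.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; `high` must be below the Nyquist
#'   frequency.
#' @param order Butterworth order (default 4).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 100, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (low <= 0 || low >= high) stop("require 0 < low < high")
  if (high >= fs / 2)
    stop("high (", high, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  x <- rec$signal
  n <- nrow(x)
  # reflective padding, >= 3 filter time constants of the low cutoff;
  # padded length rounded up to a 2-3-5-smooth FFT size
  pad_min <- min(n - 2L, ceiling(3 * fs / (2 * pi * low)))
  np <- stats::nextn(n + 2L * pad_min, c(2, 3, 5))
  if (np - n > 2L * (n - 1L)) np <- stats::nextn(n, c(2, 3, 5))
  pad <- (np - n) %/% 2L
  pad_r <- np - n - pad
  g <- filter_gain(np, fs, low, high, order)
  out <- cpp_fft_filter(x, g, pad, pad_r)
  colnames(out) <- colnames(x)
  rec$signal <- out
  rec
}

# 1-based start samples of consecutive epochs, optionally within trials
epoch_starts <- function(n, len, fs, trial_length = NULL) {
  if (is.null(trial_length) || is.na(trial_length))
    return(seq(1L, n - len + 1L, by = len))
  tlen <- round(trial_length * fs)
  per_trial <- tlen %/% len
  if (per_trial < 1L) stop("trial shorter than one epoch")
  trial_starts <- seq(1L, n - tlen + 1L, by = tlen)
  as.vector(outer(seq_len(per_trial) - 1L, trial_starts,
                  function(i, s) s + i * len))
}

# full (two-sided) FFT frequency grid for length n at sampling rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# zero-phase gain on the two-sided grid, cached per configuration
.gain_cache <- new.env(parent = emptyenv())

filter_gain <- function(np, fs, low, high, order) {
  key <- paste(np, fs, low, high, order, sep = "_")
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    # forward-backward application squares the magnitude response
    g <- butterworth_gain2(abs(fft_freqs(np, fs)), low, high, order)
    .gain_cache[[key]] <- g
  }
  g
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs; any trailing partial segment is
#' discarded.  If the recording carries a `trial_length` (a concatenation of
#' fixed-length trials), epochs are cut within trials so that no epoch spans
#' a trial boundary; pass `trial_length = NA` to ignore trial structure and
#' epoch the continuous signal.
#'
#' @param rec An `eeg_recording` at least one epoch long.
#' @param epoch_length Epoch length in seconds (default 4).
#' @param trial_length Trial length in seconds; defaults to the recording's
#'   own `trial_length` (possibly NULL = none).
#' @return An `epoch_set` with all epochs initially flagged retained.
#' @export
extract_epochs <- function(rec, epoch_length = 4,
                           trial_length = rec$trial_length) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  len <- round(epoch_length * fs)
  n <- n_samples(rec)
  if (n < len)
    stop("recording (", n, " samples) shorter than one epoch (", len, ")")
  starts <- epoch_starts(n, len, fs, trial_length)
  ep <- cpp_extract_epochs(rec$signal, starts - 1L, len)
  epoch_set(ep, epoch_length, fs, montage = rec$montage,
            subject_id = rec$subject_id, condition = rec$condition)
}

#' Peak-to-peak artifact rejection
#'
#' Flags an epoch as rejected iff any channel's peak-to-peak amplitude
#' (max minus min) within the epoch exceeds the configured threshold.
#' Deterministic and invariant to channel ordering; flags only ever move
#' from retained to rejected.
#'
#' @param es An `epoch_set`.
#' @param cfg A `preprocess_config` (threshold in microvolts).
#' @return The `epoch_set` with updated `retained` flags.
#' @export
reject_artifacts <- function(es, cfg = preprocess_config()) {
  stopifnot(inherits(es, "epoch_set"))
  thr <- cfg$reject_ptp_threshold
  ptp <- as.numeric(cpp_epoch_ptp(es$epochs))
  es$retained <- es$retained & (ptp <= thr)
  es
}

#' Minimum-clean-data retention rule
#'
#' A subject x condition enters the analysis only if at least
#' `min_clean_seconds` of artifact-free data survive rejection (boundary
#' inclusive: exactly the minimum passes).  Returns the epoch set unchanged
#' when the rule is met; otherwise returns a `subject_excluded` object
#' recording the reason, which the pipeline logs and drops.
#'
#' @param es An `epoch_set` after [reject_artifacts()].
#' @param cfg A `preprocess_config`.
#' @return The unchanged `epoch_set`, or a `subject_excluded` object.
#' @export
enforce_min_clean <- function(es, cfg = preprocess_config()) {
  stopifnot(inherits(es, "epoch_set"))
  clean <- retained_seconds(es)
  if (clean >= cfg$min_clean_seconds) return(es)
  structure(list(subject_id = es$subject_id, condition = es$condition,
                 retained_seconds = clean,
                 required_seconds = cfg$min_clean_seconds,
                 epochs_total = dim(es$epochs)[1],
                 epochs_retained = sum(es$retained)),
            class = "subject_excluded")
}

#' @rdname enforce_min_clean
#' @param x Object to test.
#' @export
is_excluded <- function(x) inherits(x, "subject_excluded")

#' @export
print.subject_excluded <- function(x, ...) {
  cat(sprintf("<subject_excluded> %s/%s: %.0f s clean < %.0f s required\n",
              x$subject_id, x$condition, x$retained_seconds,
              x$required_seconds))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Fixed order: average reference, zero-phase bandpass, epoching (within
#' trials when trial structure is known), peak-to-peak rejection, and the
#' minimum-clean-data rule.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A `preprocess_config`.
#' @return An `epoch_set`, or a `subject_excluded` object.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- average_reference(rec)
  rec <- bandpass_filter(rec, cfg$band_low, cfg$band_high, cfg$filter_order)
  es <- extract_epochs(rec, cfg$epoch_length)
  es <- reject_artifacts(es, cfg)
  enforce_min_clean(es, cfg)
}
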