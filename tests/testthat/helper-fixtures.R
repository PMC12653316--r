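# Shared fixture builders (everything is generated in code at test time).

# tiny montage for unit tests that don't need all 19 channels
mini_montage <- function(n = 3) {
  labels <- paste0("ch", seq_len(n))
  channel_montage(labels, stats::setNames(rep("frontal", n), labels))
}

# multi-tone recording over the default 19-channel montage; each tone gets
# equally spaced per-channel phases (2*pi*j/19) so the instantaneous
# channel mean is exactly zero and average referencing is a no-op
tone_recording <- function(freqs, amps, fs = 250, seconds = 60,
                           condition = "EO", subject_id = "T001") {
  m <- default_montage()
  nch <- length(m$labels)
  t <- (0:(round(seconds * fs) - 1)) / fs
  sig <- sapply(seq_len(nch), function(j) {
    rowSums(sapply(seq_along(freqs), function(k)
      amps[k] * sin(2 * pi * freqs[k] * t + 2 * pi * j / nch)))
  })
  eeg_recording(sig, fs, m, subject_id, condition)
}

# white-noise epoch set (one channel repeated across the montage)
noise_epochs <- function(sd = 1, n_epochs = 50, fs = 250, epoch_length = 4,
                         seed = 42) {
  set.seed(seed)
  m <- default_montage()
  n <- n_epochs * epoch_length * fs
  sig <- matrix(rnorm(n * 19, sd = sd), ncol = 19)
  extract_epochs(eeg_recording(sig, fs, m), epoch_length)
}

# quiet config: no artifacts, short recordings, deterministic
quiet_config <- function(n_subjects = 4, seed = 1, seconds = 64, ...) {
  sim_config(n_subjects = n_subjects, seed = seed,
             n_trials_per_condition = 2, trial_length = seconds / 2,
             artifact_rates = list(blink_per_minute = 0,
                                   emg_burst_per_minute = 0), ...)
}
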