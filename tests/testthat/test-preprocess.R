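test_that("average reference removes the channel mean and is idempotent", {
  m2 <- mini_montage(2)
  # (+1, -1) everywhere is already zero-mean: unchanged
  x <- cbind(rep(1, 10), rep(-1, 10))
  r <- eeg_recording(x, 100, m2)
  expect_equal(average_reference(r)$signal, r$signal,
               ignore_attr = TRUE)
  # adding a common offset changes nothing after referencing
  set.seed(1)
  m3 <- mini_montage(3)
  y <- matrix(rnorm(24), ncol = 3)
  r1 <- average_reference(eeg_recording(y, 100, m3))
  r2 <- average_reference(eeg_recording(y + 17.3, 100, m3))
  expect_equal(r1$signal, r2$signal, tolerance = 1e-12)
  # direct-subtraction oracle, zero row means, idempotence
  expect_equal(unname(r1$signal), unname(y - rowMeans(y)))
  expect_true(all(abs(rowMeans(r1$signal)) < 1e-12))
  expect_equal(average_reference(r1)$signal, r1$signal, tolerance = 1e-10)
  # single channel is an error
  expect_error(average_reference(eeg_recording(matrix(1:5), 100,
                                               mini_montage(1))),
               "at least 2 channels")
})

test_that("bandpass rejects DC, preserves the passband, attenuates stopbands", {
  m <- mini_montage(2)
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  # DC-only signal vanishes
  dc <- eeg_recording(matrix(50, length(t), 2), fs, m)
  out <- bandpass_filter(dc, 0.5, 100)
  mid <- out$signal[(2 * fs):(8 * fs), ]
  expect_lt(max(abs(mid)), 1)
  # 10 Hz tone passes within 5%
  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), ncol = 1)[, c(1, 1)],
                        fs, m)
  ot <- bandpass_filter(tone, 0.5, 100)$signal[(2 * fs):(8 * fs), 1]
  expect_equal(max(abs(ot)), 1, tolerance = 0.05)
  # stopband contract at the design points: low/4 and (high + Nyquist)/2
  atten_at <- function(freq, order = 4) {
    x <- eeg_recording(matrix(sin(2 * pi * freq * t), ncol = 1)[, c(1, 1)],
                       fs, m)
    o <- bandpass_filter(x, 0.5, 100, order)$signal[(2 * fs):(8 * fs), 1]
    20 * log10(sqrt(mean(o^2)) / sqrt(0.5))
  }
  expect_lt(atten_at((100 + fs / 2) / 2), -20)   # 175 Hz
  # low/4 needs a long record to measure: 60 s, edges trimmed
  t2 <- (0:(60 * fs - 1)) / fs
  slow <- eeg_recording(matrix(sin(2 * pi * 0.125 * t2), ncol = 1)[, c(1, 1)],
                        fs, m)
  os <- bandpass_filter(slow, 0.5, 100)$signal[(10 * fs):(50 * fs), 1]
  expect_lt(20 * log10(sqrt(mean(os^2)) / sqrt(0.5)), -20)
  # a 120 Hz tone is attenuated by the analytic zero-phase response
  g120 <- 1 / (1 + (120 / 100)^8)
  expect_equal(10^(atten_at(120) / 20), g120, tolerance = 0.02)
  # and is pushed past 20 dB by a higher-order configuration
  expect_lt(atten_at(120, order = 8), -20)
  # invalid upper edge
  expect_error(bandpass_filter(tone, 0.5, 300), "Nyquist")
})

test_that("zero-phase response matches forward-backward Butterworth filtering", {
  skip_if_not_installed("signal")
  set.seed(7)
  fs <- 250
  x <- rnorm(4 * fs)
  m <- mini_montage(2)
  rec <- eeg_recording(cbind(x, rev(x)), fs, m)
  ours <- bandpass_filter(rec, 1, 40)$signal[, 1]
  bf <- signal::butter(4, c(1, 40) / (fs / 2), type = "pass")
  ref <- signal::filtfilt(bf, x)
  mid <- (fs + 1):(3 * fs)      # away from edges, transients differ
  expect_gt(cor(ours[mid], ref[mid]), 0.999)
  expect_lt(sqrt(mean((ours[mid] - ref[mid])^2)) / sd(ref[mid]), 0.05)
})

test_that("epoch extraction floors partial segments and honours trials", {
  m <- default_montage()
  fs <- 250
  sig <- matrix(rnorm(30 * fs * 19), ncol = 19)
  es <- extract_epochs(eeg_recording(sig, fs, m), 4)
  expect_equal(dim(es$epochs)[1], 7)        # 30 s -> 7 epochs, 2 s dropped
  long <- matrix(rnorm(300 * fs * 19), ncol = 19)
  es75 <- extract_epochs(eeg_recording(long, fs, m), 4)
  expect_equal(dim(es75$epochs)[1], 75)     # plain floor division
  es70 <- extract_epochs(eeg_recording(long, fs, m, trial_length = 30), 4)
  expect_equal(dim(es70$epochs)[1], 70)     # 7 per 30 s trial
  expect_true(all(es$retained))
  expect_error(extract_epochs(eeg_recording(sig[1:100, ], fs, m), 4),
               "shorter than one epoch")
})

test_that("epoching then concatenating reproduces the original samples", {
  m <- default_montage()
  fs <- 250
  sig <- matrix(rnorm(10 * fs * 19), ncol = 19)
  es <- extract_epochs(eeg_recording(sig, fs, m), 2)
  rebuilt <- do.call(rbind, lapply(seq_len(dim(es$epochs)[1]), function(i)
    matrix(es$epochs[i, , ], ncol = 19)))
  expect_equal(rebuilt, unname(sig[seq_len(nrow(rebuilt)), ]))
})

test_that("peak-to-peak rejection matches a brute-force scan", {
  set.seed(11)
  m <- default_montage()
  fs <- 250
  sig <- matrix(rnorm(40 * fs * 19, sd = 30), ncol = 19)
  # plant a 400 uV blink-sized excursion inside epoch 3
  sig[2200, 4] <- sig[2200, 4] + 400
  rec <- eeg_recording(sig, fs, m)
  es <- reject_artifacts(extract_epochs(rec, 4), preprocess_config())
  brute <- sapply(seq_len(dim(es$epochs)[1]), function(i)
    max(apply(es$epochs[i, , ], 2, function(ch) max(ch) - min(ch))) <= 100)
  expect_identical(es$retained, brute)
  expect_false(es$retained[3])
  # rejection invariant to channel ordering
  perm <- sample(19)
  mp <- channel_montage(m$labels[perm],
                        m$lobe_map[m$labels[perm]])
  esp <- reject_artifacts(extract_epochs(
    eeg_recording(sig[, perm], fs, mp), 4), preprocess_config())
  expect_identical(esp$retained, es$retained)
  # flags only move retained -> rejected
  es2 <- reject_artifacts(es, preprocess_config(reject_ptp_threshold = 1e9))
  expect_identical(es2$retained, es$retained)
})

test_that("minimum-clean-data rule is boundary-inclusive", {
  m <- default_montage()
  mk <- function(n_ret, n_tot = 50) {
    ep <- array(0, c(n_tot, 1000, 19))
    epoch_set(ep, 4, 250, m, retained = seq_len(n_tot) <= n_ret)
  }
  cfg <- preprocess_config()
  expect_s3_class(enforce_min_clean(mk(45), cfg), "epoch_set")   # 180 s
  expect_s3_class(enforce_min_clean(mk(15), cfg), "epoch_set")   # 60 s exact
  out <- enforce_min_clean(mk(14), cfg)                          # 56 s
  expect_true(is_excluded(out))
  expect_equal(out$epochs_retained, 14)
})

test_that("config invariants are enforced", {
  expect_error(preprocess_config(band_low = 0), "band_low")
  expect_error(preprocess_config(min_clean_seconds = 2, epoch_length = 4),
               "min_clean_seconds")
})
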