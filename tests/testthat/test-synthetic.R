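test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(sampling_rate = 100), "sampling_rate")
  expect_error(sim_config(n_trials_per_condition = 1, trial_length = 10),
               "n_trials_per_condition")
  expect_error(sim_config(alpha_reactivity = 0.9), "alpha_reactivity")
  expect_error(sim_config(planted_slopes = list(thalamus = -0.1)),
               "unknown lobe")
})

test_that("metadata is deterministic and extensible per subject", {
  cfg <- sim_config(n_subjects = 12, seed = 5)
  m1 <- simulate_metadata(cfg)
  m2 <- simulate_metadata(cfg)
  expect_identical(m1, m2)
  # adding subjects does not reshuffle the existing ones
  cfg_big <- sim_config(n_subjects = 20, seed = 5)
  m3 <- simulate_metadata(cfg_big)
  expect_identical(m1, m3[seq_len(12), ])
  # ranges and derived grouping
  expect_true(all(m1$oab > 0))
  expect_true(all(m1$kmmse >= 0 & m1$kmmse <= 30))
  expect_identical(m1$amyloid_group, ifelse(m1$oab >= 0.78, "high", "low"))
})

test_that("amyloid-group split matches the analytic lognormal tail", {
  cfg <- sim_config(n_subjects = 10000, seed = 31)
  md <- simulate_metadata(cfg)
  p <- 1 - plnorm(cfg$cutoff, cfg$oab_distribution$meanlog,
                  cfg$oab_distribution$sdlog)   # closed-form oracle
  n_high <- sum(md$oab >= cfg$cutoff)
  ci <- qbinom(c(0.005, 0.995), 10000, p)
  expect_gte(n_high, ci[1])
  expect_lte(n_high, ci[2])
})

test_that("recordings are deterministic and conditions are checked", {
  cfg <- quiet_config(seed = 8)
  md <- simulate_metadata(cfg)
  r1 <- simulate_recording(md[1, ], "EC", cfg)
  r2 <- simulate_recording(md[1, ], "EC", cfg)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_recording(md[1, ], "EO", cfg)
  expect_false(identical(r1$signal, r3$signal))
  expect_error(simulate_recording(md[1, ], "eyes-shut", cfg),
               "unknown condition")
})

test_that("artifact-free recordings stay inside the clean amplitude envelope", {
  cfg <- quiet_config(n_subjects = 3, seed = 21)
  md <- simulate_metadata(cfg)
  for (i in 1:3) {
    rec <- simulate_recording(md[i, ], "EC", cfg)
    expect_lt(max(abs(rec$signal)), 150)
  }
})

test_that("injected blinks are large frontal transients at the set rate", {
  cfg <- sim_config(n_subjects = 2, seed = 13, n_trials_per_condition = 2,
                    trial_length = 32,
                    artifact_rates = list(blink_per_minute = 6,
                                          emg_burst_per_minute = 0))
  md <- simulate_metadata(cfg)
  rec <- simulate_recording(md[1, ], "EO", cfg)
  # blink amplitude >= 300 uV survives on Fp1/Fp2 even after referencing
  fp <- abs(average_reference(rec)$signal[, c("Fp1", "Fp2")])
  expect_gt(max(fp), 300)
  # a clean sibling config has no such excursion
  cfg0 <- quiet_config(n_subjects = 2, seed = 13)
  rec0 <- simulate_recording(simulate_metadata(cfg0)[1, ], "EO", cfg0)
  expect_lt(max(abs(rec0$signal)), 150)
})

test_that("null model: zero slopes and zero noise give identical log-TBR", {
  cfg <- quiet_config(n_subjects = 6, seed = 4, ratio_noise_sd = 0)
  md <- simulate_metadata(cfg)
  vals <- sapply(1:6, function(i) {
    es <- preprocess_recording(simulate_recording(md[i, ], "EC", cfg))
    rr <- lobar_ratios(es)
    rr$log_tbr[rr$lobe == "parietal"]
  })
  # identical planted targets; spread is spectral-estimation error only
  expect_lt(diff(range(vals)), 0.05)
  expect_equal(mean(vals), cfg$planted_intercepts[["parietal"]],
               tolerance = 0.02)
})

test_that("planted coupling: Monte-Carlo mean matches the linear predictor", {
  cfg <- sim_config(n_subjects = 400, seed = 17,
                    planted_slopes = list(parietal = c(EO = 0, EC = -0.06)))
  fixed_oab <- 1.5
  draws <- sapply(1:400, function(i) {
    subj <- list(subject_id = sprintf("S%04d", i), oab = fixed_oab)
    planted_log_ratios(subj, "EC", cfg)$log_tbr[4]  # parietal row
  })
  predicted <- cfg$planted_intercepts[["parietal"]] - 0.06 * fixed_oab
  expect_equal(mean(draws), predicted,
               tolerance = 3 * cfg$ratio_noise_sd / sqrt(400))
})

test_that("planted-ratio table and the signal path share the same draws", {
  cfg <- quiet_config(n_subjects = 3, seed = 19)
  md <- simulate_metadata(cfg)
  tab <- simulate_planted_ratios(cfg, md, conditions = "EC")
  tg <- planted_log_ratios(md[2, ], "EC", cfg)
  sub <- tab[tab$subject_id == md$subject_id[2], ]
  expect_equal(sub$log_tbr, tg$log_tbr)
  expect_equal(sub$log_tar, tg$log_tar)
  # and the synthesised signal reproduces them through the pipeline
  es <- preprocess_recording(simulate_recording(md[2, ], "EC", cfg))
  rr <- lobar_ratios(es)
  expect_equal(rr$log_tbr[match(tg$lobe, rr$lobe)], tg$log_tbr,
               tolerance = 0.05)
})

test_that("alpha power is higher eyes-closed than eyes-open", {
  cfg <- quiet_config(n_subjects = 4, seed = 23)
  md <- simulate_metadata(cfg)
  alpha_power <- function(i, cond) {
    es <- preprocess_recording(simulate_recording(md[i, ], cond, cfg))
    rbp <- relative_band_power(welch_psd(es))
    mean(rbp$rel_power[rbp$band == "alpha"])
  }
  for (i in 1:4)
    expect_gt(alpha_power(i, "EC"), alpha_power(i, "EO"))
})

test_that("spectral targeting: a dominant oscillator peaks in its own band", {
  # push nearly all oscillatory power into theta and check the Welch peak
  cfg <- quiet_config(n_subjects = 2, seed = 29,
                      planted_intercepts = c(frontal = 2, central = 2,
                                             temporal = 2, parietal = 2,
                                             occipital = 2),
                      planted_intercepts_tar = c(frontal = 2, central = 2,
                                                 temporal = 2, parietal = 2,
                                                 occipital = 2),
                      ratio_noise_sd = 0, delta_weight = 0.01,
                      pink_power = 0.1)
  md <- simulate_metadata(cfg)
  es <- preprocess_recording(simulate_recording(md[1, ], "EO", cfg))
  psd <- welch_psd(es)
  peak <- psd$frequencies[which.max(psd$power["Pz", ])]
  expect_gte(peak, 4); expect_lt(peak, 8)
})
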