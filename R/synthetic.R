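#' Simulation configuration for a synthetic qEEG cohort
#'
#' Defines the study conditions the generator emulates: resting-state
#' recordings of ten 30 s trials per condition at 250 Hz over the 19-channel
#' 10-20 montage, a lognormal plasma oligomeric amyloid-beta (OAB)
#' distribution straddling the 0.78 ng/mL clinical cutoff, and a planted
#' linear coupling between OAB and lobar log10-TBR with Gaussian residual
#' noise.  The planted linear predictor is the ground truth that parameter-
#' recovery tests measure the pipeline against.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Master seed; all per-subject streams derive from it, so a
#'   cohort can be extended without reshuffling existing subjects.
#' @param sampling_rate Hz (default 250; must exceed 200 so the 0.5-100 Hz
#'   analysis range is below Nyquist).
#' @param n_trials_per_condition,trial_length Default 10 trials x 30 s per
#'   condition; total duration per condition must be at least 60 s.
#' @param oab_distribution List `(meanlog, sdlog)` of the lognormal OAB
#'   distribution in ng/mL (default centred at the cutoff: meanlog
#'   log(0.78), sdlog 0.6, giving a realistic 0.2-2.5 ng/mL bulk range).
#' @param cutoff Dichotomisation cutoff in ng/mL (default 0.78).
#' @param planted_slopes Named list `lobe -> c(EO =, EC =)` slope of
#'   log10-TBR per ng/mL OAB (default all zero).
#' @param planted_intercepts Named numeric, per-lobe log10-TBR intercepts
#'   (defaults on the scale of published elderly cohort summaries).
#' @param planted_slopes_tar,planted_intercepts_tar Same for log10-TAR.
#' @param ratio_noise_sd Residual SD of the planted log10 ratios (default
#'   0.33 log10 units).
#' @param artifact_rates List `(blink_per_minute, emg_burst_per_minute)`
#'   (defaults 4 and 2, yielding roughly 45 artifact-free 4 s epochs out of
#'   75 per 300 s condition at the default rejection threshold).
#' @param blink_amplitude Blink peak amplitude in microvolts (default 400,
#'   so the default 100 uV peak-to-peak rejection always catches it).
#' @param covariate_model List with `age_mean`, `age_sd`, `education_probs`
#'   (four education categories: <=6, 7-9, 10-12, >12 years), `kmmse_mean`,
#'   `kmmse_sd`, `female_prob`.
#' @param alpha_reactivity Multiplicative eyes-closed over eyes-open alpha
#'   amplitude factor (> 1; default 1.5).
#' @param osc_power Total oscillatory band power per channel in uV^2
#'   (default 60).
#' @param pink_power Total 1/f background power in the 0.5-100 Hz range in
#'   uV^2 (default 5; kept well below `osc_power` so band-power targets are
#'   dominated by the controlled oscillators).
#' @param delta_weight Delta band power as a fraction of theta (default 0.8).
#' @param confound_strength If non-zero, couples age and K-MMSE to OAB
#'   (standardised units per ng/mL) for covariate-adjustment testing;
#'   default 0 (covariates independent of OAB, matching null group
#'   differences in typical aging cohorts).
#' @param compensate_reference If `TRUE` (default), pre-compensates channel
#'   spectra for the linear mixing that average re-referencing applies, so
#'   post-reference band powers equal the planted targets exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 174,
                       seed = 1L,
                       sampling_rate = 250,
                       n_trials_per_condition = 10,
                       trial_length = 30,
                       oab_distribution = list(meanlog = log(0.78),
                                               sdlog = 0.6),
                       cutoff = 0.78,
                       planted_slopes = NULL,
                       planted_intercepts = c(frontal = 0.77, central = 0.55,
                                              temporal = 0.74, parietal = 0.59,
                                              occipital = 0.70),
                       planted_slopes_tar = NULL,
                       planted_intercepts_tar = c(frontal = 0.21,
                                                  central = 0.04,
                                                  temporal = 0.04,
                                                  parietal = 0.01,
                                                  occipital = -0.15),
                       ratio_noise_sd = 0.33,
                       artifact_rates = list(blink_per_minute = 4,
                                             emg_burst_per_minute = 2),
                       blink_amplitude = 400,
                       covariate_model = list(age_mean = 74.87, age_sd = 8.52,
                                              education_probs = c(0.2414, 0.2701,
                                                                  0.1552, 0.3333),
                                              kmmse_mean = 23.4, kmmse_sd = 4.8,
                                              female_prob = 0.707),
                       alpha_reactivity = 1.5,
                       osc_power = 60,
                       pink_power = 5,
                       delta_weight = 0.8,
                       confound_strength = 0,
                       compensate_reference = TRUE) {
  lobes <- names(planted_intercepts)
  zero_slopes <- lapply(stats::setNames(lobes, lobes),
                        function(l) c(EO = 0, EC = 0))
  planted_slopes <- merge_slopes(zero_slopes, planted_slopes)
  planted_slopes_tar <- merge_slopes(zero_slopes, planted_slopes_tar)
  cfg <- as.list(environment())
  cfg$lobes <- NULL
  cfg$zero_slopes <- NULL
  validate_sim_config(structure(cfg, class = "sim_config"))
}

merge_slopes <- function(base, user) {
  if (is.null(user)) return(base)
  for (lb in names(user)) {
    if (!lb %in% names(base))
      stop("planted slope for unknown lobe: ", lb)
    v <- user[[lb]]
    if (is.null(names(v)) && length(v) == 1) v <- c(EO = v, EC = v)
    base[[lb]][names(v)] <- v
  }
  base
}

validate_sim_config <- function(cfg) {
  check <- function(ok, field, why)
    if (!ok) stop("invalid sim_config field '", field, "': ", why,
                  call. = FALSE)
  check(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 2,
        "n_subjects", "need at least 2 subjects")
  check(cfg$sampling_rate > 200, "sampling_rate",
        "must exceed 200 Hz so Nyquist covers the 0.5-100 Hz range")
  check(cfg$n_trials_per_condition * cfg$trial_length >= 60,
        "n_trials_per_condition",
        "need at least 60 s of signal per condition")
  check(cfg$trial_length > 0, "trial_length", "must be positive")
  check(is.list(cfg$oab_distribution) &&
          all(c("meanlog", "sdlog") %in% names(cfg$oab_distribution)) &&
          cfg$oab_distribution$sdlog > 0,
        "oab_distribution", "need meanlog and positive sdlog")
  check(cfg$cutoff > 0, "cutoff", "must be positive")
  check(cfg$ratio_noise_sd >= 0, "ratio_noise_sd", "must be non-negative")
  check(all(unlist(cfg$artifact_rates) >= 0), "artifact_rates",
        "rates must be non-negative")
  check(cfg$alpha_reactivity > 1, "alpha_reactivity", "must exceed 1")
  check(cfg$osc_power > 0, "osc_power", "must be positive")
  check(cfg$pink_power > 0, "pink_power", "must be positive")
  cfg
}

# --- deterministic RNG streams ---------------------------------------------

# 31-bit string hash, exact in double arithmetic
hash31 <- function(key) {
  h <- 5381
  for (c in utf8ToInt(key)) h <- (h * 33 + c) %% 2147483647
  as.integer(h)
}

# evaluate expr under a deterministic child stream, restoring caller RNG
with_stream <- function(cfg, ..., expr) {
  key <- paste(c(format(cfg$seed), ...), collapse = "/")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(hash31(key))
  expr
}

# --- subject metadata -------------------------------------------------------

#' Simulate subject metadata
#'
#' Draws demographic and biomarker records: age, sex, education years (a
#' four-category mixture reproducing the typical split below-elementary /
#' middle / high / post-secondary), K-MMSE, and lognormal plasma OAB with
#' the dichotomised amyloid group (`high` iff OAB >= cutoff).  Covariates
#' are independent of OAB unless `confound_strength` is set.  Deterministic
#' given the config seed, per subject.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `subject_id`, `age`, `sex`,
#'   `education_years`, `kmmse`, `oab`, `amyloid_group`.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cm <- config$covariate_model
  rows <- lapply(seq_len(config$n_subjects), function(i) {
    sid <- sprintf("S%04d", i)
    with_stream(config, sid, "metadata", expr = {
      oab <- stats::rlnorm(1, config$oab_distribution$meanlog,
                           config$oab_distribution$sdlog)
      age <- stats::rnorm(1, cm$age_mean, cm$age_sd)
      kmmse <- stats::rnorm(1, cm$kmmse_mean, cm$kmmse_sd)
      if (config$confound_strength != 0) {
        d <- config$confound_strength * (oab - config$cutoff)
        age <- age + d * cm$age_sd
        kmmse <- kmmse - d * cm$kmmse_sd
      }
      edu_cat <- sample.int(4, 1, prob = cm$education_probs)
      edu <- switch(edu_cat, sample(2:6, 1), sample(7:9, 1),
                    sample(10:12, 1), sample(14:18, 1))
      data.frame(subject_id = sid,
                 age = round(min(max(age, 55), 95)),
                 sex = if (stats::runif(1) < cm$female_prob) "female" else "male",
                 education_years = edu,
                 kmmse = round(min(max(kmmse, 0), 30)),
                 oab = oab,
                 amyloid_group = if (oab >= config$cutoff) "high" else "low",
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

# --- planted ratio targets --------------------------------------------------

#' Planted lobar log-ratio targets for one subject and condition
#'
#' The generating model of the simulator: per lobe,
#' `log10 TBR = intercept + slope * OAB + eps` with `eps ~ N(0,
#' ratio_noise_sd)` drawn per subject x condition, and `log10 TAR =
#' intercept + slope_tar * OAB + reactivity shift + eps_tar` with `eps_tar`
#' shared between conditions so eyes-closed alpha enhancement is preserved
#' per subject.  These targets are embedded in the synthetic signals by
#' [simulate_recording()] and are the ground truth for recovery tests.
#'
#' @param subject One row of [simulate_metadata()] output (or a list with
#'   `subject_id` and `oab`).
#' @param condition `"EO"` or `"EC"`.
#' @param config A [sim_config()].
#' @return data.frame with columns `lobe`, `log_tbr`, `log_tar`.
#' @export
planted_log_ratios <- function(subject, condition, config) {
  lobes <- names(config$planted_intercepts)
  eps_tbr <- with_stream(config, subject$subject_id, condition, "tbr-noise",
                         expr = stats::rnorm(length(lobes),
                                             0, config$ratio_noise_sd))
  eps_tar <- with_stream(config, subject$subject_id, "tar-noise",
                         expr = stats::rnorm(length(lobes),
                                             0, config$ratio_noise_sd))
  shift <- log10(config$alpha_reactivity) / 2 *
    if (condition == "EC") -1 else 1
  sl_tbr <- vapply(lobes, function(l) config$planted_slopes[[l]][[condition]],
                   numeric(1))
  sl_tar <- vapply(lobes,
                   function(l) config$planted_slopes_tar[[l]][[condition]],
                   numeric(1))
  data.frame(lobe = lobes,
             log_tbr = config$planted_intercepts[lobes] +
               sl_tbr * subject$oab + eps_tbr,
             log_tar = config$planted_intercepts_tar[lobes] +
               sl_tar * subject$oab + shift + eps_tar,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Planted ratio records for a whole cohort
#'
#' Returns the generator's lobar log-ratio draws directly as a ratio table
#' (one row per subject x condition x lobe), bypassing signal synthesis.
#' This is the exact generating model of the signal path -
#' [simulate_recording()] embeds these same draws in its spectra - so it is
#' the appropriate input for large statistical simulations (type-I error,
#' power) where synthesising hours of multichannel EEG would add nothing
#' but Welch estimation noise.
#'
#' @param config A [sim_config()].
#' @param metadata Optional precomputed [simulate_metadata()] output.
#' @param conditions Conditions to emit (default both).
#' @return data.frame with columns `subject_id`, `condition`, `lobe`,
#'   `tar`, `tbr`, `log_tar`, `log_tbr`.
#' @export
simulate_planted_ratios <- function(config, metadata = NULL,
                                    conditions = c("EO", "EC")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(metadata)) metadata <- simulate_metadata(config)
  out <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(seq_len(nrow(metadata)), function(i) {
      t <- planted_log_ratios(metadata[i, ], cond, config)
      data.frame(subject_id = metadata$subject_id[i], condition = cond,
                 lobe = t$lobe, tar = 10^t$log_tar, tbr = 10^t$log_tbr,
                 log_tar = t$log_tar, log_tbr = t$log_tbr,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# --- signal synthesis -------------------------------------------------------

# synthesis carrier bands, inset 1 Hz from the analysis band edges so that
# Welch leakage stays inside the band the oscillator targets
synth_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             lo = c(1.5, 5, 9, 14), hi = c(3, 7, 12, 29))
}

# frequency-grid constants reused across recordings of equal length
.synth_cache <- new.env(parent = emptyenv())

synth_grid <- function(n, fs, pink_power) {
  key <- paste(n, fs, pink_power, sep = "_")
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  df <- fs / n
  nf <- n %/% 2 - 1L
  f <- df * seq_len(nf)
  pink_shape <- ifelse(f >= 0.5 & f <= 100, 1 / f, 0)
  pink <- pink_shape * (pink_power / (sum(pink_shape) * df))
  ab <- default_bands(); sb <- synth_bands()
  smask <- lapply(seq_len(4), function(b) which(f >= sb$lo[b] & f <= sb$hi[b]))
  pink_in_band <- vapply(seq_len(4), function(b)
    sum(pink[f >= ab$f_low[b] & f < ab$f_high[b]]) * df, numeric(1))
  out <- list(pink = pink, smask = smask,
              n_smask = lengths(smask), pink_in_band = pink_in_band)
  .synth_cache[[key]] <- out
  out
}

#' Simulate one resting-state EEG recording
#'
#' Synthesises a continuous 19-channel recording whose expected spectra are
#' a weak 1/f (pink) background plus four band-limited stochastic
#' oscillators (delta, theta, alpha, beta), with per-channel band powers
#' chosen so that the lobar relative-power ratios equal the planted targets
#' of [planted_log_ratios()] exactly: theta/alpha/beta/delta weights are
#' solved from the target TAR and TBR, normalised to a fixed total
#' oscillatory power, corrected for the 1/f content inside each analysis
#' band, and (by default) pre-compensated for average-reference mixing.
#' Oscillators are realised by random-phase spectral synthesis (band-limited
#' noise with exactly the target band power).  Eye-blink and EMG transients
#' are injected at the configured rates.  Deterministic given (seed,
#' subject_id, condition).
#'
#' @param subject One row of [simulate_metadata()] output.
#' @param condition `"EO"` or `"EC"`.
#' @param config A [sim_config()].
#' @return An `eeg_recording` (microvolts) carrying the trial length.
#' @export
simulate_recording <- function(subject, condition, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!condition %in% c("EO", "EC"))
    stop("unknown condition: ", condition)
  fs <- config$sampling_rate
  montage <- default_montage()
  nch <- length(montage$labels)
  n <- round(config$n_trials_per_condition * config$trial_length * fs)
  df <- fs / n
  nf <- n %/% 2 - 1L                    # positive, non-Nyquist bins
  f <- df * seq_len(nf)

  targets <- planted_log_ratios(subject, condition, config)
  band_totals <- channel_band_totals(targets, montage, config)  # 4 x nch

  # desired PSD per channel: pink background + rectangular band bumps
  gr <- synth_grid(n, fs, config$pink_power)
  S <- matrix(gr$pink, nrow = nf, ncol = nch)
  for (b in seq_len(4)) {
    osc <- pmax(band_totals[b, ] - gr$pink_in_band[b], 0.01)
    S[gr$smask[[b]], ] <- S[gr$smask[[b]], ] +
      rep(osc / (gr$n_smask[b] * df), each = gr$n_smask[b])
  }
  if (isTRUE(config$compensate_reference)) {
    a <- 1 - 2 / nch; bb <- 1 / nch^2
    c1 <- a; c2 <- bb / (a + nch * bb); floor_v <- 1e-12
  } else {
    c1 <- 1; c2 <- 0; floor_v <- 0
  }

  phases <- with_stream(config, subject$subject_id, condition, "phases",
                        expr = matrix(stats::runif(nf * nch, 0, 2 * pi),
                                      nrow = nf))
  x <- cpp_synth_from_psd(S, phases, n, c1, c2, floor_v, n * sqrt(df / 2))
  colnames(x) <- montage$labels

  rec <- eeg_recording(x, fs, montage, subject$subject_id, condition,
                       trial_length = config$trial_length)
  inject_artifacts(rec, config)
}

# per-channel analysis-band power totals (uV^2) realising the lobar targets
channel_band_totals <- function(targets, montage, config) {
  nch <- length(montage$labels)
  out <- matrix(0, nrow = 4, ncol = nch,
                dimnames = list(c("delta", "theta", "alpha", "beta"),
                                montage$labels))
  for (i in seq_len(nrow(targets))) {
    r_b <- 10^targets$log_tbr[i]
    r_a <- 10^targets$log_tar[i]
    w <- c(delta = config$delta_weight, theta = 1,
           alpha = 1 / r_a, beta = 1 / r_b)
    chans <- lobe_channels(montage, targets$lobe[i])
    out[, chans] <- w * (config$osc_power / sum(w))
  }
  out
}


# --- artifact injection -----------------------------------------------------

# biphasic blink kernel (unit peak), duration in samples
blink_kernel <- function(len) {
  t <- seq(0, 1, length.out = len)
  main <- sin(pi * pmin(t / 0.6, 1))^2
  rebound <- -0.35 * sin(pi * pmax((t - 0.6) / 0.4, 0))^2
  main + rebound
}

blink_topography <- function(labels) {
  w <- stats::setNames(rep(0.05, length(labels)), labels)
  w[c("Fp1", "Fp2")] <- 1
  w[c("F3", "F4", "F7", "F8", "Fz")] <- 0.3
  w
}

inject_artifacts <- function(rec, config) {
  rates <- config$artifact_rates
  if (all(unlist(rates) == 0)) return(rec)
  fs <- rec$sampling_rate
  n <- n_samples(rec)
  minutes <- n / fs / 60
  labels <- rec$montage$labels
  with_stream(config, rec$subject_id, rec$condition, "artifacts", expr = {
    n_blink <- stats::rpois(1, rates$blink_per_minute * minutes)
    n_emg <- stats::rpois(1, rates$emg_burst_per_minute * minutes)
    blen <- round(0.4 * fs)
    if (n_blink > 0) {
      kern <- blink_kernel(blen)
      topo <- blink_topography(labels)
      starts <- sort(sample.int(n - blen, n_blink))
      for (s in starts) {
        amp <- config$blink_amplitude * stats::runif(1, 1, 1.3)
        rec$signal[s:(s + blen - 1L), ] <- rec$signal[s:(s + blen - 1L), ] +
          outer(kern * amp, topo)
      }
    }
    elen <- round(0.5 * fs)
    if (n_emg > 0) {
      emg_chans <- c("T3", "T4", "F7", "F8", "Fp1", "Fp2")
      starts <- sample.int(n - elen, n_emg)
      tt <- seq_len(elen) / fs
      env <- sin(pi * seq_len(elen) / elen)^2
      for (s in starts) {
        ch <- sample(emg_chans, 1)
        freqs <- stats::runif(4, 35, 80)
        ph <- stats::runif(4, 0, 2 * pi)
        burst <- env * colSums(matrix(
          sin(outer(freqs, tt, function(fr, t) 2 * pi * fr * t) + ph),
          nrow = 4)) * 55
        rec$signal[s:(s + elen - 1L), ch] <-
          rec$signal[s:(s + elen - 1L), ch] + burst
      }
    }
    rec
  })
}

#' Simulate a full cohort of recordings
#'
#' Convenience wrapper: metadata plus one recording per subject and
#' condition, returned as nested lists (or written to `out_dir` as
#' delimited matrices plus a metadata CSV via [write_cohort()]).
#'
#' @param config A [sim_config()].
#' @param conditions Conditions to generate (default both).
#' @return List with elements `metadata` and `recordings` (a list indexed
#'   `recordings[[subject_id]][[condition]]`).
#' @export
simulate_cohort <- function(config, conditions = c("EO", "EC")) {
  metadata <- simulate_metadata(config)
  recordings <- lapply(seq_len(nrow(metadata)), function(i) {
    recs <- lapply(conditions, function(cond)
      simulate_recording(metadata[i, ], cond, config))
    stats::setNames(recs, conditions)
  })
  names(recordings) <- metadata$subject_id
  list(metadata = metadata, recordings = recordings)
}
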