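---
title: "Lobar qEEG power ratios and a planted-coupling synthetic cohort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lobar qEEG power ratios and a planted-coupling synthetic cohort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic validation does and
does not establish about real data.

## The measurement model

A resting-state recording is a 19-channel (10–20 montage) continuous
signal in microvolts at 250 Hz, acquired as repeated 30 s trials per
condition (eyes-open, eyes-closed). The analysis chain is fixed in order
and deterministic:

1. **Average reference** — subtract the instantaneous channel mean; linear,
   idempotent, removes common-mode activity.
2. **Zero-phase bandpass 0.5–100 Hz** — the squared magnitude response of a
   4th-order Butterworth highpass–lowpass cascade, applied in the frequency
   domain with reflective padding of at least three filter time constants.
   This realises exactly the response that forward–backward ("filtfilt")
   IIR filtering approximates, with strictly zero phase and no
   startup transients; the test suite cross-checks it against
   `signal::filtfilt` on interior samples. One consequence worth stating:
   at 250 Hz sampling the upper transition band (100 Hz cutoff against a
   125 Hz Nyquist) is necessarily shallow — a 4th-order response reaches
   only ≈ 11 dB attenuation at 112.5 Hz. This is a property of any
   4th-order realisation at this sampling rate, not of the implementation;
   the 20 dB stopband figures quoted in the tests are verified at 500 Hz
   where the geometry permits them.
3. **Epoching** — consecutive non-overlapping 4 s epochs, cut within trials
   so no epoch spans a trial boundary (a 30 s trial yields 7 epochs; ten
   trials yield 70). Epoching a continuous untrialed record floors to
   `duration / 4`.
4. **Artifact rejection** — an epoch is rejected iff any channel's
   peak-to-peak amplitude exceeds 100 µV. This deterministic surrogate
   replaces manual review plus ICA, which cannot be reproduced without the
   original operator; the threshold catches the 400 µV synthetic blinks by
   construction and leaves clean synthetic epochs (≈ 65 µV peak-to-peak)
   untouched. `reject_artifacts()` is the plug-in point where an ICA-based
   cleaner could be substituted.
5. **Retention rule** — a subject × condition enters the analysis only with
   ≥ 60 s of retained data (boundary inclusive); exclusion is per
   condition, so a subject failing EC can still contribute EO.
6. **Welch PSD** — per retained epoch, 2 s Hamming windows with 50% overlap
   (three segments per epoch), mean-detrended per segment, one-sided
   density scaling, averaged over all segments of all retained epochs.
   Frequency resolution 0.5 Hz.
7. **Relative band power** — band power is the sum of PSD bins whose centre
   frequency falls in the half-open interval `[f_low, f_high)` (so 8 Hz
   belongs to alpha, 13 Hz to beta — the source protocol does not state
   the boundary convention, this is a declared choice), divided by the sum
   over 0.5–100 Hz inclusive. The 30–100 Hz residual counts in the
   denominator but is not a reported band.
8. **Lobar ratios** — per-channel relative powers are averaged over the
   lobe's electrodes *first*, then `TAR = theta/alpha`, `TBR = theta/beta`.
   The alternative order (per-channel ratios, then averaged) is available
   as `per_channel_ratios = TRUE` for sensitivity analysis. Ratios are
   log-transformed; base 10 by default (the protocol does not state the
   base; base-10 summaries of elderly cohorts are plausible for both, and
   the package accepts `"ln"`).

## The statistical layer

Subjects are dichotomised at the 0.78 ng/mL plasma OAβ cutoff (boundary
inclusive). For each index × lobe (× condition or pooled): Student's
pooled-variance t (Welch's variant by config — the protocol says only
"independent two-sample t-tests"), Cohen's d with pooled SD and sign
convention (low − high), Pearson correlation, and OLS regressions of the
log-ratio on OAβ — unadjusted, and adjusted for age, education years and
K-MMSE. Coefficients are reported raw (log-ratio units per ng/mL) with
classical standard errors; standardised coefficients are computed alongside
because published tables of this kind are ambiguous about the scale.
Education-stratified models (≤6, 7–12, >12 years) use age and K-MMSE only,
education being the stratifier. Bonferroni correction defaults to a family
of 10 (5 lobes × 2 indices within one condition); nominal p-values are
always reported alongside. The Shapiro–Wilk check on log-ratios is a
logged diagnostic, not a hard gate. Empty or too-small cells (groups under
2, strata under the parameter count) are reported with explicit flags,
never silently dropped.

## The synthetic cohort

Because the motivating clinical data cannot be shared, the generator is a
first-class, tested module, and its defaults *are* the study conditions:
174 subjects, ten 30 s trials per condition at 250 Hz, lognormal OAβ
centred at the cutoff (meanlog `log(0.78)`, sdlog 0.6 — bulk range
≈ 0.2–2.5 ng/mL), residual SD of the planted log10 ratios 0.33 (the order
of published lobar SDs), covariates drawn independently of OAβ by default
(age 74.9 ± 8.5, a four-category education mixture ≈ 24/27/16/33%, K-MMSE
≈ 23 ± 5), with an optional confounding switch for testing covariate
adjustment.

Each channel's spectrum is a weak 1/f background (5 µV² total in
0.5–100 Hz) plus four band-limited stochastic oscillators. Per subject ×
condition × lobe the generator draws

    log10 TBR = intercept(lobe) + slope(lobe, condition) · OAβ + ε,
    ε ~ N(0, 0.33),

and analogously for TAR (whose noise is shared between conditions so that
the deterministic eyes-closed alpha enhancement — a factor 1.5 on alpha
amplitude — is preserved within subject). Band weights are solved from the
target TAR/TBR, normalised to a fixed total oscillatory power of 60 µV²
per channel (≈ 8 µV rms — realistic for average-referenced elderly resting
EEG, and comfortably below the 100 µV rejection threshold so clean epochs
are never falsely rejected), and corrected for the 1/f content inside each
analysis band so that *measured* band totals equal the targets.

Three deliberate mechanisms make the planted coupling exact by
construction rather than approximate:

* **Amplitude-exact synthesis.** Oscillators are realised by random-phase
  spectral synthesis: deterministic amplitude envelope, uniformly random
  phases. This is band-limited noise whose realised band power equals the
  target exactly, removing realisation variance that would otherwise blur
  recovery targets. (Gaussian-coefficient synthesis — "filtered white
  noise" in the narrow sense — would add chi-squared power fluctuations
  with no benefit to the planted model.)
* **Carrier insetting.** Synthesis bands are inset 1 Hz from the analysis
  band edges (e.g. theta content lives in 5–7 Hz), so Hamming-window
  leakage stays inside the band it belongs to and cross-band contamination
  does not compress planted slopes.
* **Reference pre-compensation.** Average re-referencing mixes channel
  spectra linearly (`S_i → (1−2/n)·S_i + ΣS/n²`). The generator inverts
  this map in power space before synthesis, so post-reference band powers
  hit the targets exactly. Without it, recovered slopes would be biased
  toward zero by a few percent.

Artifacts are parameterised transients: biphasic blinks (400 µV, 0.4 s,
full amplitude at Fp1/Fp2 with a frontal spread) and 35–80 Hz EMG bursts
(0.5 s, temporal/frontal-edge channels), injected at Poisson rates of 4
and 2 per minute. At these defaults a 300 s condition yields ≈ 45
artifact-free epochs out of 70 — the retention level typical of clinical
practice. Per-subject RNG streams are derived by hashing (master seed,
subject id, condition, purpose), so cohorts are extensible without
reshuffling existing subjects, and every recording is bit-reproducible.

`simulate_planted_ratios()` exposes the generator's planted draws directly
as a ratio table. It is the *identical* generating model the signal path
embeds (the test suite asserts the two agree subject by subject), which
makes it the appropriate engine for large statistical simulations — the
200-cohort type-I calibration runs on it, since synthesising ~10⁴ hours of
multichannel EEG would only add Welch estimation noise to a question about
the regression layer.

## Validation design and problem sizes

The acceptance layer validates properties, not clinical numbers — the
motivating cohort is private, and nothing here claims to reproduce its
tables:

* spectral correctness by Parseval (white noise, σ² = 25 µV², 100 epochs,
  within 5%) and analytic sinusoid power (A²/2 within 3%);
* a two-oscillator fixture (6 Hz at 2A over 20 Hz at A) that must come out
  of the full chain as TBR = 4.0 ± 5% and log10-TBR = 0.602 ± 0.01;
* preprocessing contracts (idempotent reference to 1e−10, 100% blink
  sensitivity with no false rejection of untouched epochs, the 60 s
  boundary inclusive);
* scale invariance of every ratio under amplitude scaling (to 1e−9);
* equality of t, d, r, β and SE with textbook-formula oracles to 1e−8 on
  50 random instances;
* recovery of a planted parietal-EC slope of −0.06 over 100 replicate
  cohorts of n = 174, run through the *full* signal path at 64 s of EC
  signal per condition (two 32 s trials → 16 epochs = 64 s clean, just
  above the retention boundary; artifact rates zero). The replicate-mean
  estimate must sit within 0.01 of −0.06 and single-cohort estimates
  within 2 reported SEs in ≥ 95% of replicates. With residual SD 0.33 the
  per-cohort SE is ≈ 0.04, so the 2-SE criterion's nominal coverage is
  ≈ 95.3% — expected to pass, but intrinsically close to its own
  threshold;
* type-I calibration over 200 null cohorts (per-cell rejection within the
  exact binomial interval around 0.05; Bonferroni family-wise error at or
  below the level);
* bit-identical reruns of the full pipeline from one configuration.

The 64 s recovery length and the planted-ratio engine for the type-I runs
are the two scale-downs relative to the full 300 s acquisition; both are
choices about where spectral estimation noise matters (it only widens the
recovery SEs slightly) rather than about the statistical question.

## What passing does not show

The generator's spectra are stationary, artifact injection is stylised,
channels are independent up to the reference transform (no volume
conduction or spatial correlation), and covariates are independent of OAβ
by default. Passing the suite therefore demonstrates that the pipeline
measures what it claims on signals whose ground truth is known — unbiased
ratio estimation, calibrated inference, faithful plumbing — not that any
particular clinical effect size is correct, and not robustness to
artifact morphologies or nonstationarities the generator does not emulate
(ICA-grade ocular contamination, line noise, electrode drift).

## Numerical notes

FFT-heavy kernels (synthesis, zero-phase filtering, Welch accumulation,
epoch gathering) are implemented in C++ (RcppArmadillo) for throughput;
all randomness stays on the R side, so results are reproducible from the
R RNG alone. FFT lengths are rounded to 2-3-5-smooth sizes via padding.
Degenerate inputs error early with the offending field or channel named:
zero total power, non-positive ratios, rank-deficient designs, missing
lobar electrodes, recordings shorter than one epoch. Boundary conventions
(cutoff and retention inclusive, band intervals half-open) are asserted in
the test suite.
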