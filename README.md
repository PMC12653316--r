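# qeegratios

Resting-state quantitative EEG (qEEG) pipeline for lobar spectral power
ratios and their association with a plasma amyloid biomarker, with a
synthetic-cohort generator that makes the whole analysis testable end to
end without access to clinical recordings.

## The problem

In aging and early Alzheimer's disease, cortical rhythms slow: spectral
mass shifts from the faster alpha (8–13 Hz) and beta (13–30 Hz) bands
toward theta (4–8 Hz). Two summary indices capture this — the
theta-to-alpha ratio (TAR) and the theta-to-beta ratio (TBR) — computed
from relative band powers of resting-state EEG recorded eyes-open (EO) and
eyes-closed (EC). A blood-based marker of oligomeric amyloid-β (OAβ,
ng/mL, clinical cutoff 0.78 ng/mL) offers a cheap peripheral measure of
amyloid burden. The scientific question is whether lobar log-ratios are
linearly associated with plasma OAβ after adjusting for age, education and
global cognition (K-MMSE).

For each retained subject × condition, the pipeline computes per channel
the Welch power spectral density (2 s Hamming windows, 50% overlap, over
artifact-free 4 s epochs), normalises band power to total 0.5–100 Hz
power, averages relative powers over five lobar electrode groups of the
19-channel 10–20 montage, and forms

    TAR = theta / alpha,   TBR = theta / beta,   both log10-transformed.

The statistical layer then mirrors a standard biomarker-association plan:
dichotomised group comparisons (Student's t, Cohen's d), Pearson
correlations, unadjusted and covariate-adjusted OLS regressions of
log-ratio on OAβ, education-stratified models (≤6, 7–12, >12 years), and
Bonferroni correction over the 5 lobes × 2 indices family.

Because clinical EEG of this kind is not publicly shareable, the package
ships a generator that synthesises multichannel recordings with a known
1/f + band-limited-oscillator spectral structure and a *planted* linear
coupling between OAβ and lobar log10-TBR. The planted model is the ground
truth against which the full pipeline is validated (parameter recovery,
type-I error calibration).

## Worked example

Simulate a 40-subject cohort with a slope of −0.12 log10-TBR per ng/mL
planted in the central and parietal lobes (EC), run the full pipeline, and
look at the EC TBR regressions:

```r
library(qeegratios)
cfg <- sim_config(n_subjects = 40, seed = 7,
                  planted_slopes = list(parietal = c(EO = 0, EC = -0.12),
                                        central  = c(EO = 0, EC = -0.12)))
res <- run_pipeline(pipeline_config(sim = cfg))
subset(res$tables$regressions, index == "TBR" & condition == "EC")
```

```
<pipeline_result> 40 subjects, 400 ratio records, 0 excluded
      lobe      model      beta     se p_value n_used
   frontal unadjusted  0.049558 0.0773   0.526     40
   frontal   adjusted  0.000312 0.0816   0.997     40
   central unadjusted -0.125800 0.0761   0.107     40
   central   adjusted -0.097929 0.0818   0.239     40
  temporal unadjusted -0.039729 0.0712   0.580     40
  temporal   adjusted -0.017146 0.0764   0.824     40
  parietal unadjusted -0.050877 0.0867   0.561     40
  parietal   adjusted -0.047520 0.0924   0.610     40
 occipital unadjusted  0.019800 0.0732   0.788     40
 occipital   adjusted  0.002211 0.0785   0.978     40
```

Reading this: `beta` is the OLS coefficient of log10-TBR on OAβ (log-ratio
units per ng/mL); the planted central/parietal slopes are recovered with
the right sign but, at n = 40 and residual SD 0.33, they sit within their
standard errors of zero — single small cohorts are underpowered, which is
exactly why the acceptance layer aggregates 100 replicate cohorts at
n = 174. The log-transformed ratios pass the Shapiro–Wilk normality gate
(e.g. parietal EC: W = 0.960, p = 0.17).

A cohort can also be written to disk and re-analysed from files
(`write_cohort()`, `run_pipeline()` with `input_dir`), and a thin CLI
wrapper lives at `inst/scripts/qeeg-pipeline.R`
(`generate` / `run` subcommands).

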