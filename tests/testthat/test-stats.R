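# textbook-formula oracles, independent of the implementation path
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2),
       d = (mean(a) - mean(b)) / sqrt(sp2))
}
oracle_r <- function(x, y) {
  r <- cov(x, y) / (sd(x) * sd(y))
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}
oracle_ols <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(XtXi) * s2))
}

test_that("dichotomisation is boundary-inclusive at the cutoff", {
  expect_equal(dichotomize(0.78), "high")
  expect_equal(dichotomize(0.50), "low")
  expect_equal(dichotomize(1.20), "high")
  expect_equal(dichotomize(c(0.1, 0.78, 2)), c("low", "high", "high"))
  expect_error(dichotomize(-1), "positive")
})

test_that("two-sample t and Cohen's d match hand formulas", {
  r <- two_sample_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$cohen_d, -2)
  expect_equal(r$t_statistic, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohen_d, 0)
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = 0.5)
    got <- two_sample_t(a, b)
    want <- oracle_t(a, b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$cohen_d, want$d, tolerance = 1e-10)
  }
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("Pearson correlation matches its closed form", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  set.seed(15)
  a <- rnorm(50); b <- 0.3 * a + rnorm(50)
  got <- pearson(a, b)
  want <- oracle_r(a, b)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_error(pearson(a, rep(1, 50)), "constant")
})

test_that("linear models recover noiseless coefficients and match OLS oracle", {
  oab <- runif(40, 0.2, 2.5)
  f <- suppressWarnings(fit_linear_model(3 - 0.06 * oab, oab))
  expect_equal(f$beta, -0.06, tolerance = 1e-10)
  expect_equal(f$model, "unadjusted")
  set.seed(16)
  for (i in 1:10) {
    X <- data.frame(oab = runif(50, 0.2, 2.5), age = rnorm(50, 75, 8),
                    education_years = rnorm(50, 11, 4), kmmse = rnorm(50, 23, 5))
    y <- 0.5 - 0.06 * X$oab + 0.01 * X$age + rnorm(50, sd = 0.3)
    got <- fit_linear_model(y, X$oab, X[, -1])
    want <- oracle_ols(y, X)
    expect_equal(got$beta, unname(want$beta[2]), tolerance = 1e-8)
    expect_equal(got$se, unname(want$se[2]), tolerance = 1e-8)
  }
  # rank-deficient design errors, naming the collinear column
  X2 <- data.frame(age = rnorm(30), age2 = NA)
  X2$age2 <- X2$age * 2
  expect_error(fit_linear_model(rnorm(30), rnorm(30), X2), "age2")
  # standardised coefficient equals beta * sd(x)/sd(y)
  x <- runif(60); y <- 1 - 0.3 * x + rnorm(60, sd = 0.1)
  g <- fit_linear_model(y, x)
  expect_equal(g$beta_standardized, g$beta * sd(x) / sd(y), tolerance = 1e-10)
})

test_that("education strata split at 6 and 12 years", {
  s <- education_strata(c(4, 9, 15))
  expect_equal(as.character(s), c("<=6", "7-12", ">12"))
  expect_equal(as.character(education_strata(c(6, 7, 12, 13))),
               c("<=6", "7-12", "7-12", ">12"))
})

test_that("Bonferroni multiplies and caps at one", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  set.seed(17)
  p <- runif(10)
  expect_equal(bonferroni(p, 12), pmin(1, p * 12))
  expect_error(bonferroni(1.2, 5), "0, 1")
  expect_error(bonferroni(runif(5), 3), "family_size")
})

test_that("Shapiro-Wilk gate behaves on null, alternative and degenerate input", {
  set.seed(18)
  sw <- shapiro_wilk(rnorm(200))
  expect_true(sw$W > 0 && sw$W <= 1)
  # strong lognormal alternative: essentially always rejected at n = 200
  rej <- sum(replicate(20, shapiro_wilk(rlnorm(200, 0, 1))$p_value < 0.05))
  expect_gte(rej, 19)
  # approximate null calibration
  null_rej <- mean(replicate(200, shapiro_wilk(rnorm(100))$p_value < 0.05))
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(null_rej, ci[1]); expect_lte(null_rej, ci[2])
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(1, 10)))
})

test_that("report tables have stable shapes and honest group statistics", {
  cfg <- sim_config(n_subjects = 60, seed = 41)
  md <- simulate_metadata(cfg)
  recs <- simulate_planted_ratios(cfg, md)
  gc <- group_comparison(recs, md, analysis_config(), "pooled")
  expect_equal(nrow(gc), 10)                   # 2 indices x 5 lobes
  expect_true(all(gc$p_value >= 0 & gc$p_value <= 1))
  expect_true(all(gc$sd_low >= 0 & gc$sd_high >= 0))
  ct <- correlation_table(recs, md)
  expect_equal(nrow(ct), 20)                   # x 2 conditions
  expect_true(all(abs(ct$r) <= 1))
  rt <- regression_table(recs, md)
  expect_equal(nrow(rt), 40)                   # x 2 models
  expect_true(all(rt$p_bonferroni >= rt$p_value))
  expect_true(all(rt$n_used == 60))
  st <- stratified_regression_table(recs, md)
  expect_equal(nrow(st), 120)                  # x 3 strata
  expect_true(all(c("stratum", "insufficient_n") %in% names(st)))
})

test_that("empty education strata are flagged, not dropped", {
  cfg <- sim_config(n_subjects = 30, seed = 43)
  md <- simulate_metadata(cfg)
  md$education_years <- 9                      # everyone mid-stratum
  recs <- simulate_planted_ratios(cfg, md, conditions = "EC")
  st <- stratified_regression_table(recs, md, conditions = "EC")
  lo <- st[st$stratum == "<=6", ]
  expect_true(all(lo$insufficient_n))
  expect_true(all(is.na(lo$beta)))
  mid <- st[st$stratum == "7-12", ]
  expect_false(any(mid$insufficient_n))
})

test_that("a slope planted only in one stratum is recovered there alone", {
  set.seed(19)
  n <- 240
  md <- data.frame(subject_id = sprintf("S%04d", 1:n),
                   age = rnorm(n, 75, 8),
                   education_years = sample(c(4, 9, 15), n, replace = TRUE),
                   kmmse = rnorm(n, 23, 5),
                   oab = rlnorm(n, log(0.78), 0.6))
  slope <- -0.25
  low_edu <- md$education_years <= 6
  recs <- data.frame(subject_id = md$subject_id, condition = "EC",
                     lobe = "central",
                     log_tar = rnorm(n, 0, 0.2),
                     log_tbr = 0.55 + slope * md$oab * low_edu +
                       rnorm(n, 0, 0.2))
  recs$tar <- 10^recs$log_tar; recs$tbr <- 10^recs$log_tbr
  st <- stratified_regression_table(recs, md, conditions = "EC")
  tbr <- st[st$index == "TBR" & st$model == "adjusted", ]
  b_lo <- tbr[tbr$stratum == "<=6", ]
  b_hi <- tbr[tbr$stratum == ">12", ]
  expect_lt(abs(b_lo$beta - slope), 2 * b_lo$se)
  expect_lt(abs(b_hi$beta), 2.5 * b_hi$se)
})

test_that("adding an independent covariate leaves the slope unbiased", {
  set.seed(20)
  reps <- 200
  deltas <- replicate(reps, {
    oab <- rlnorm(80, log(0.78), 0.6)
    junk <- rnorm(80)
    y <- 0.5 - 0.06 * oab + rnorm(80, sd = 0.3)
    fit_linear_model(y, oab, data.frame(junk = junk))$beta
  })
  expect_lt(abs(mean(deltas) + 0.06), 3 * sd(deltas) / sqrt(reps))
})

test_that("slope estimates concentrate with growing cohorts", {
  errs <- sapply(c(100, 400, 1600), function(n) {
    cfg <- sim_config(n_subjects = n, seed = 47,
                      planted_slopes = list(parietal = c(EO = 0, EC = -0.06)))
    md <- simulate_metadata(cfg)
    recs <- simulate_planted_ratios(cfg, md, conditions = "EC")
    s <- merge(recs[recs$lobe == "parietal", ], md, by = "subject_id")
    abs(fit_linear_model(s$log_tbr, s$oab)$beta + 0.06)
  })
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 0.02)           # no blow-up as n grows
})
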