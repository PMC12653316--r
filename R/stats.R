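#' Analysis configuration for the statistical layer
#'
#' @param cutoff Dichotomisation cutoff for plasma OAB in ng/mL
#'   (default 0.78; `high` group iff OAB >= cutoff, boundary inclusive).
#' @param covariates Covariates of the adjusted models (default age,
#'   education years, K-MMSE).
#' @param alpha_level Two-tailed significance level (default 0.05).
#' @param bonferroni_family_size Number of tests in the correction family
#'   (default 10 = 5 lobes x 2 indices within one condition; set 20 to pool
#'   conditions).
#' @param education_breaks Stratum bounds in years: strata are
#'   `<= breaks[1]`, `(breaks[1], breaks[2]]`, `> breaks[2]`
#'   (default 6 and 12, i.e. <=6 / 7-12 / >12).
#' @param stratified_covariates Covariates used inside education strata
#'   (default age and K-MMSE; education is the stratifier, not a covariate).
#' @param t_variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cutoff = 0.78,
                            covariates = c("age", "education_years", "kmmse"),
                            alpha_level = 0.05,
                            bonferroni_family_size = 10,
                            education_breaks = c(6, 12),
                            stratified_covariates = c("age", "kmmse"),
                            t_variant = c("student", "welch")) {
  stopifnot(cutoff > 0, alpha_level > 0, alpha_level < 1,
            length(education_breaks) == 2,
            education_breaks[1] < education_breaks[2])
  t_variant <- match.arg(t_variant)
  structure(list(cutoff = cutoff, covariates = covariates,
                 alpha_level = alpha_level,
                 bonferroni_family_size = bonferroni_family_size,
                 education_breaks = education_breaks,
                 stratified_covariates = stratified_covariates,
                 t_variant = t_variant),
            class = "analysis_config")
}

#' Dichotomise a biomarker value at a cutoff
#'
#' @param oab Positive biomarker value(s) in ng/mL.
#' @param cutoff Cutoff in ng/mL (default 0.78).
#' @return `"high"` iff `oab >= cutoff` (boundary inclusive), else `"low"`.
#' @export
dichotomize <- function(oab, cutoff = 0.78) {
  if (any(oab <= 0)) stop("oab must be positive")
  ifelse(oab >= cutoff, "high", "low")
}

#' Shapiro-Wilk normality check
#'
#' Diagnostic gate on the log-transformed ratio values; logged, not a hard
#' stop.  Errors on degenerate (constant) input, mirroring the underlying
#' test's requirement of non-zero variance.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3) stop("Shapiro-Wilk requires n >= 3")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Two-sample comparison of low vs high amyloid groups
#'
#' Independent two-sample t-test (Student's pooled-variance by default,
#' Welch optional) plus Cohen's d with the pooled standard deviation.
#' Sign convention: statistics are (low - high), so positive d means the
#' low-OAB group has the larger mean.
#'
#' @param low_values,high_values Numeric vectors, each n >= 2.
#' @param t_variant `"student"` or `"welch"`.
#' @return List with group means/SDs, `t_statistic`, `df`, `p_value`,
#'   `cohen_d`.
#' @export
two_sample_t <- function(low_values, high_values,
                         t_variant = c("student", "welch")) {
  t_variant <- match.arg(t_variant)
  if (length(low_values) < 2 || length(high_values) < 2)
    stop("each group needs n >= 2")
  tt <- stats::t.test(low_values, high_values,
                      var.equal = (t_variant == "student"))
  n1 <- length(low_values); n2 <- length(high_values)
  sp <- sqrt(((n1 - 1) * stats::var(low_values) +
              (n2 - 1) * stats::var(high_values)) / (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (mean(low_values) - mean(high_values)) / sp
  list(mean_low = mean(low_values), sd_low = stats::sd(low_values),
       mean_high = mean(high_values), sd_high = stats::sd(high_values),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohen_d = d)
}

#' Pearson correlation between the biomarker and a log ratio
#'
#' @param oab Numeric vector (ng/mL).
#' @param log_ratio Numeric vector, same length.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(oab, log_ratio) {
  if (length(oab) != length(log_ratio)) stop("length mismatch")
  if (length(oab) < 3) stop("need n >= 3")
  if (stats::sd(oab) == 0 || stats::sd(log_ratio) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(oab, log_ratio, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(oab))
}

#' Linear association between a log ratio and the biomarker
#'
#' Ordinary least squares of the log-transformed ratio on OAB, optionally
#' with covariates (the adjusted model).  Reports the OAB coefficient on
#' the raw scale (log-ratio units per ng/mL) with its classical standard
#' error and two-sided p, plus the standardised coefficient (all variables
#' scaled to unit SD) as a secondary quantity.  Complete cases only.
#'
#' @param y Dependent values (log ratio).
#' @param oab Biomarker values (ng/mL).
#' @param covariates Optional data.frame or matrix of covariate columns.
#' @return List of class `regression_result`: `beta`, `se`, `p_value`,
#'   `beta_standardized`, `covariate_estimates`, `n_used`, `model`.
#' @export
fit_linear_model <- function(y, oab, covariates = NULL) {
  dat <- data.frame(y = y, oab = oab)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  p <- ncol(dat)                       # parameters incl. intercept
  if (n_used <= p + 1)
    stop("too few complete cases (", n_used, ") for ", p, " parameters")
  fit <- stats::lm(y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  zdat <- as.data.frame(scale(dat))
  zfit <- stats::lm(y ~ ., data = zdat)
  structure(list(beta = sm["oab", "Estimate"],
                 se = sm["oab", "Std. Error"],
                 p_value = sm["oab", "Pr(>|t|)"],
                 beta_standardized = unname(stats::coef(zfit)["oab"]),
                 covariate_estimates = sm[setdiff(rownames(sm),
                                                  c("(Intercept)", "oab")),
                                          "Estimate"],
                 intercept = sm["(Intercept)", "Estimate"],
                 n_used = n_used,
                 model = if (is.null(covariates)) "unadjusted" else "adjusted"),
            class = "regression_result")
}

#' Assign education strata
#'
#' @param education_years Numeric vector of education in years.
#' @param breaks Two bounds (default 6 and 12): strata `<=6`, `7-12`, `>12`.
#' @return Factor with levels `"<=6"`, `"7-12"`, `">12"` (for default
#'   breaks).
#' @export
education_strata <- function(education_years, breaks = c(6, 12)) {
  labels <- c(paste0("<=", breaks[1]),
              paste0(breaks[1] + 1, "-", breaks[2]),
              paste0(">", breaks[2]))
  cut(education_years, c(-Inf, breaks, Inf), labels = labels)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * family_size)`; the family size may exceed the number
#' of p-values supplied (tests belonging to the same family reported
#' elsewhere).
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param family_size Number of tests in the family (>= `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  if (family_size < length(p_values))
    stop("family_size must be at least the number of p-values")
  pmin(1, p_values * family_size)
}

# --- table-level drivers over a cohort's ratio records ----------------------

merge_ratios_metadata <- function(records, metadata) {
  m <- merge(records, metadata, by = "subject_id")
  if (nrow(m) == 0) stop("no overlap between ratio records and metadata")
  m
}

#' Group comparison tables (low vs high amyloid)
#'
#' For each index (TAR, TBR) and lobe, compares log-ratio values between
#' the low- and high-OAB groups: group means and SDs, Student's t, p, and
#' Cohen's d.
#'
#' @param records Ratio records (`subject_id`, `condition`, `lobe`,
#'   `log_tar`, `log_tbr`).
#' @param metadata Subject metadata with `oab`.
#' @param config An [analysis_config()].
#' @param condition `"EO"`, `"EC"`, or `"pooled"` (average of a subject's
#'   conditions).
#' @return data.frame, one row per index x lobe.
#' @export
group_comparison <- function(records, metadata, config = analysis_config(),
                             condition = "pooled") {
  m <- prepare_condition(records, metadata, condition)
  m$group <- dichotomize(m$oab, config$cutoff)
  out <- lapply(c(log_tar = "log_tar", log_tbr = "log_tbr"), function(col) {
    do.call(rbind, lapply(unique(m$lobe), function(lb) {
      s <- m[m$lobe == lb, ]
      lo <- s[[col]][s$group == "low"]
      hi <- s[[col]][s$group == "high"]
      r <- if (length(lo) >= 2 && length(hi) >= 2) {
        two_sample_t(lo, hi, config$t_variant)
      } else {
        # degenerate group: report means, no test
        list(mean_low = mean(lo), sd_low = stats::sd(lo),
             mean_high = mean(hi), sd_high = stats::sd(hi),
             t_statistic = NA_real_, p_value = NA_real_,
             cohen_d = NA_real_)
      }
      data.frame(index = toupper(sub("log_", "", col)), lobe = lb,
                 condition = condition,
                 mean_total = mean(s[[col]]), sd_total = stats::sd(s[[col]]),
                 mean_low = r$mean_low, sd_low = r$sd_low,
                 mean_high = r$mean_high, sd_high = r$sd_high,
                 t_statistic = r$t_statistic, p_value = r$p_value,
                 cohen_d = r$cohen_d, n_low = length(lo),
                 n_high = length(hi), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

prepare_condition <- function(records, metadata, condition) {
  if (condition == "pooled") {
    agg <- stats::aggregate(cbind(log_tar, log_tbr) ~ subject_id + lobe,
                            data = records, FUN = mean)
  } else {
    agg <- records[records$condition == condition,
                   c("subject_id", "lobe", "log_tar", "log_tbr")]
    if (nrow(agg) == 0) stop("no records for condition ", condition)
  }
  merge_ratios_metadata(agg, metadata)
}

#' Correlation table by lobe and condition
#'
#' Pearson r (and p) between OAB and each log ratio, per lobe x condition.
#'
#' @inheritParams group_comparison
#' @param conditions Conditions to include (default EO and EC).
#' @return data.frame, one row per index x lobe x condition.
#' @export
correlation_table <- function(records, metadata,
                              conditions = c("EO", "EC")) {
  out <- do.call(rbind, lapply(conditions, function(cond) {
    m <- prepare_condition(records, metadata, cond)
    do.call(rbind, lapply(c(log_tar = "log_tar", log_tbr = "log_tbr"),
      function(col) {
        do.call(rbind, lapply(unique(m$lobe), function(lb) {
          s <- m[m$lobe == lb, ]
          r <- if (nrow(s) >= 3 && stats::sd(s$oab) > 0 &&
                     stats::sd(s[[col]]) > 0) {
            pearson(s$oab, s[[col]])
          } else list(r = NA_real_, p_value = NA_real_, n = nrow(s))
          data.frame(index = toupper(sub("log_", "", col)), lobe = lb,
                     condition = cond, r = r$r, p_value = r$p_value,
                     n = r$n, stringsAsFactors = FALSE)
        }))
      }))
  }))
  rownames(out) <- NULL
  out
}

#' Regression tables: unadjusted and covariate-adjusted models
#'
#' Per index x lobe x condition, fits the unadjusted model (intercept +
#' OAB) and the adjusted model (plus the configured covariates), reporting
#' the OAB coefficient, SE, p, the standardised coefficient, and n.
#'
#' @inheritParams correlation_table
#' @param config An [analysis_config()].
#' @return data.frame, one row per index x lobe x condition x model.
#' @export
regression_table <- function(records, metadata, config = analysis_config(),
                             conditions = c("EO", "EC")) {
  out <- do.call(rbind, lapply(conditions, function(cond) {
    m <- prepare_condition(records, metadata, cond)
    do.call(rbind, lapply(c(log_tar = "log_tar", log_tbr = "log_tbr"),
      function(col) {
        do.call(rbind, lapply(unique(m$lobe), function(lb) {
          s <- m[m$lobe == lb, ]
          do.call(rbind, lapply(c("unadjusted", "adjusted"), function(mod) {
            covs <- if (mod == "adjusted")
              s[, config$covariates, drop = FALSE] else NULL
            npar <- 2 + length(config$covariates) * (mod == "adjusted")
            if (nrow(s) <= npar + 1) {
              return(data.frame(index = toupper(sub("log_", "", col)),
                                lobe = lb, condition = cond, model = mod,
                                beta = NA_real_, se = NA_real_,
                                p_value = NA_real_,
                                beta_standardized = NA_real_,
                                n_used = nrow(s), stringsAsFactors = FALSE))
            }
            f <- fit_linear_model(s[[col]], s$oab, covs)
            data.frame(index = toupper(sub("log_", "", col)), lobe = lb,
                       condition = cond, model = mod, beta = f$beta,
                       se = f$se, p_value = f$p_value,
                       beta_standardized = f$beta_standardized,
                       n_used = f$n_used, stringsAsFactors = FALSE)
          }))
        }))
      }))
  }))
  # family = lobes x indices within one condition and model (default 10)
  out$p_bonferroni <- pmin(1, out$p_value * config$bonferroni_family_size)
  rownames(out) <- NULL
  out
}

#' Education-stratified regression tables
#'
#' Splits subjects into education strata (default <=6, 7-12, >12 years) and
#' fits the unadjusted and adjusted models within each stratum; inside
#' strata the adjusted model controls for age and K-MMSE only (education is
#' the stratifier).  Strata too small to fit are reported with an explicit
#' `insufficient_n` flag rather than silently omitted.
#'
#' @inheritParams regression_table
#' @return data.frame, one row per index x lobe x condition x stratum x
#'   model.
#' @export
stratified_regression_table <- function(records, metadata,
                                        config = analysis_config(),
                                        conditions = c("EO", "EC")) {
  out <- do.call(rbind, lapply(conditions, function(cond) {
    m <- prepare_condition(records, metadata, cond)
    m$stratum <- education_strata(m$education_years, config$education_breaks)
    do.call(rbind, lapply(c(log_tar = "log_tar", log_tbr = "log_tbr"),
      function(col) {
        do.call(rbind, lapply(unique(m$lobe), function(lb) {
          do.call(rbind, lapply(levels(m$stratum), function(st) {
            s <- m[m$lobe == lb & m$stratum == st, ]
            do.call(rbind, lapply(c("unadjusted", "adjusted"), function(mod) {
              covs <- if (mod == "adjusted")
                s[, config$stratified_covariates, drop = FALSE] else NULL
              npar <- 2 + if (mod == "adjusted")
                length(config$stratified_covariates) else 0
              if (nrow(s) <= npar + 1) {
                data.frame(index = toupper(sub("log_", "", col)), lobe = lb,
                           condition = cond, stratum = st, model = mod,
                           beta = NA_real_, se = NA_real_,
                           p_value = NA_real_, n_used = nrow(s),
                           insufficient_n = TRUE, stringsAsFactors = FALSE)
              } else {
                f <- fit_linear_model(s[[col]], s$oab, covs)
                data.frame(index = toupper(sub("log_", "", col)), lobe = lb,
                           condition = cond, stratum = st, model = mod,
                           beta = f$beta, se = f$se, p_value = f$p_value,
                           n_used = f$n_used, insufficient_n = FALSE,
                           stringsAsFactors = FALSE)
              }
            }))
          }))
        }))
      }))
  }))
  rownames(out) <- NULL
  out
}
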