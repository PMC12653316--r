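#' Lobar band power
#'
#' Unweighted arithmetic mean of per-channel relative band power over the
#' electrodes of one cortical lobe.
#'
#' @param rbp A `relative_band_power` table.
#' @param montage A `channel_montage`.
#' @param lobe Lobe name (`"frontal"`, `"central"`, `"temporal"`,
#'   `"parietal"`, `"occipital"`).
#' @return Named numeric vector, one mean relative power per band.
#' @export
lobar_band_power <- function(rbp, montage = default_montage(), lobe) {
  stopifnot(inherits(rbp, "relative_band_power"))
  chans <- lobe_channels(montage, lobe)
  missing <- setdiff(chans, unique(rbp$channel))
  if (length(missing))
    stop("missing electrode(s) for lobe ", lobe, ": ",
         paste(missing, collapse = ", "))
  sub <- rbp[rbp$channel %in% chans, ]
  c(tapply(sub$rel_power, sub$band, mean)[unique(rbp$band)])
}

#' Theta-alpha and theta-beta ratios
#'
#' TAR = theta / alpha and TBR = theta / beta, formed from lobar mean
#' relative band powers.  Elevated values indicate a shift of spectral mass
#' from the faster alpha/beta rhythms towards theta (cortical slowing).
#'
#' @param lobar_powers Named numeric vector with at least `theta`, `alpha`,
#'   `beta` entries (as returned by [lobar_band_power()]).
#' @return Named list with elements `tar` and `tbr`.
#' @export
compute_ratios <- function(lobar_powers) {
  need <- c("theta", "alpha", "beta")
  if (!all(need %in% names(lobar_powers)))
    stop("lobar_powers must contain theta, alpha and beta")
  th <- unname(lobar_powers["theta"])
  al <- unname(lobar_powers["alpha"])
  be <- unname(lobar_powers["beta"])
  if (al <= 0 || be <= 0)
    stop("zero alpha or beta denominator (degenerate spectrum)")
  list(tar = th / al, tbr = th / be)
}

#' Logarithm of a power ratio
#'
#' Base-10 by default (configurable to natural log); monotone, and turns
#' the multiplicative ratio scale into an additive one so that downstream
#' parametric statistics apply.
#'
#' @param ratio Positive unitless ratio (vectorised).
#' @param base `"log10"` (default) or `"ln"`.
#' @return Log-transformed value(s).
#' @export
log_ratio <- function(ratio, base = c("log10", "ln")) {
  base <- match.arg(base)
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be positive and finite")
  if (base == "log10") log10(ratio) else log(ratio)
}

#' Lobar ratio records for one preprocessed recording
#'
#' Runs Welch PSD and relative band power on an epoch set, then emits one
#' record per lobe with TAR, TBR and their log transforms.
#'
#' @param es An `epoch_set` surviving [enforce_min_clean()].
#' @param bands Band definitions (default [default_bands()]).
#' @param normalization_range Hz range for relative power (default 0.5-100).
#' @param window_length,overlap Welch parameters (defaults 2 s, 0.5).
#' @param log_base `"log10"` or `"ln"`.
#' @param per_channel_ratios If `TRUE`, form TAR/TBR per channel first and
#'   average the ratios over the lobe (sensitivity variant); default
#'   averages band powers over the lobe first, then forms the ratio.
#' @return data.frame with columns `subject_id`, `condition`, `lobe`,
#'   `tar`, `tbr`, `log_tar`, `log_tbr`.
#' @export
lobar_ratios <- function(es, bands = default_bands(),
                         normalization_range = c(0.5, 100),
                         window_length = 2, overlap = 0.5,
                         log_base = c("log10", "ln"),
                         per_channel_ratios = FALSE) {
  log_base <- match.arg(log_base)
  psd <- welch_psd(es, window_length, overlap)
  rbp <- relative_band_power(psd, bands, normalization_range)
  ratios_from_rbp(rbp, es$montage, es$subject_id, es$condition,
                  log_base, per_channel_ratios)
}

ratios_from_rbp <- function(rbp, montage, subject_id, condition,
                            log_base = "log10", per_channel_ratios = FALSE) {
  rr <- vapply(montage$lobes, function(lb) {
    if (per_channel_ratios) {
      chans <- lobe_channels(montage, lb)
      pc <- vapply(chans, function(ch) {
        p <- rbp[rbp$channel == ch, ]
        v <- stats::setNames(p$rel_power, p$band)
        unlist(compute_ratios(v))
      }, numeric(2))
      c(tar = mean(pc["tar", ]), tbr = mean(pc["tbr", ]))
    } else {
      unlist(compute_ratios(lobar_band_power(rbp, montage, lb)))
    }
  }, numeric(2))
  data.frame(subject_id = subject_id, condition = condition,
             lobe = montage$lobes, tar = rr["tar", ], tbr = rr["tbr", ],
             log_tar = log_ratio(rr["tar", ], log_base),
             log_tbr = log_ratio(rr["tbr", ], log_base),
             row.names = NULL, stringsAsFactors = FALSE)
}
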