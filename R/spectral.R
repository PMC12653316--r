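#' Welch power spectral density over retained epochs
#'
#' Estimates the one-sided PSD of each channel by Welch's method: every
#' retained epoch is split into overlapping segments (default 2 s windows,
#' 50% overlap, so three segments per 4 s epoch), each segment is mean-
#' detrended, Hamming-windowed, and its modified periodogram is computed;
#' the estimate is the average over all segments of all retained epochs.
#' Rejected epochs contribute nothing.  Density scaling: the sum of the PSD
#' times the bin width equals signal power in microvolts squared (Parseval,
#' up to the removed per-segment mean).
#'
#' @param es An `epoch_set` with at least one retained epoch.
#' @param window_length Welch window length in seconds (default 2); the
#'   frequency resolution is `1/window_length`.
#' @param overlap Fractional overlap of consecutive windows (default 0.5).
#' @return An object of class `psd_estimate`: list with `frequencies` (Hz),
#'   `power` (channel x frequency matrix, uV^2/Hz), `window_length`,
#'   `overlap_fraction`, `n_epochs_averaged`, `montage`.
#' @export
welch_psd <- function(es, window_length = 2, overlap = 0.5) {
  stopifnot(inherits(es, "epoch_set"))
  keep <- which(es$retained)
  if (length(keep) == 0) stop("no retained epochs to average")
  fs <- es$sampling_rate
  L <- round(window_length * fs)
  ep_len <- dim(es$epochs)[2]
  if (L > ep_len) stop("window_length exceeds epoch length")
  step <- max(1L, round(L * (1 - overlap)))
  seg_starts <- seq(1L, ep_len - L + 1L, by = step)
  w <- hamming_window(L)
  nf <- L %/% 2 + 1L
  power <- t(cpp_welch_power(es$epochs, keep - 1L, seg_starts - 1L,
                             L, w, fs))
  rownames(power) <- es$montage$labels
  structure(list(frequencies = (0:(nf - 1L)) / window_length,
                 power = power, window_length = window_length,
                 overlap_fraction = overlap,
                 n_epochs_averaged = length(keep),
                 montage = es$montage),
            class = "psd_estimate")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d ch x %d freqs (0-%g Hz, df=%g), %d epochs averaged\n",
    nrow(x$power), ncol(x$power), max(x$frequencies),
    1 / x$window_length, x$n_epochs_averaged))
  invisible(x)
}

#' Relative band power
#'
#' Per channel, sums PSD bins whose centre frequency falls in each band
#' (half-open `[f_low, f_high)`) and divides by the sum over the
#' normalisation range (default 0.5-100 Hz, endpoints inclusive).  Values
#' are unitless fractions in `[0, 1]`; any disjoint band partition covering
#' the normalisation range sums to 1.  Invariant to global amplitude
#' scaling and to the density-scaling convention (both cancel in the ratio).
#'
#' @param psd A `psd_estimate`.
#' @param bands Band definition data.frame (see [default_bands()]).
#' @param normalization_range Length-2 numeric, Hz (default `c(0.5, 100)`).
#' @return A data.frame of class `relative_band_power`: one row per
#'   channel x band with columns `channel`, `band`, `rel_power`.
#' @export
relative_band_power <- function(psd, bands = default_bands(),
                                normalization_range = c(0.5, 100)) {
  stopifnot(inherits(psd, "psd_estimate"))
  validate_bands(bands)
  f <- psd$frequencies
  eps <- 1e-9
  if (normalization_range[1] < min(f) - eps ||
      normalization_range[2] > max(f) + eps)
    stop("normalization range outside the frequency grid")
  norm_mask <- f >= normalization_range[1] - eps &
               f <= normalization_range[2] + eps
  total <- rowSums(psd$power[, norm_mask, drop = FALSE])
  if (any(total <= 0))
    stop("zero total power in normalization range (degenerate signal)")
  nb <- nrow(bands)
  nch <- nrow(psd$power)
  rel <- vapply(seq_len(nb), function(i) {
    m <- f >= bands$f_low[i] - eps & f < bands$f_high[i] - eps
    rowSums(psd$power[, m, drop = FALSE]) / total
  }, numeric(nch))
  out <- data.frame(channel = rep(rownames(psd$power), times = nb),
                    band = rep(bands$band, each = nch),
                    rel_power = as.vector(rel),
                    stringsAsFactors = FALSE)
  class(out) <- c("relative_band_power", "data.frame")
  out
}
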