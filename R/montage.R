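#' Standard 19-channel 10-20 montage with lobar grouping
#'
#' Builds the channel montage used throughout the pipeline: an ordered set of
#' electrode labels from the international 10-20 system and a map assigning
#' every electrode to one of five cortical lobes (frontal, central, temporal,
#' parietal, occipital).  Lobar ratio indices are averages of relative band
#' power over these electrode groups.
#'
#' @param labels Character vector of channel labels, in recording order.
#' @param lobe_map Named character vector mapping every label to a lobe name.
#'   Must cover each label exactly once.
#'
#' @return An object of class `channel_montage`: a list with elements
#'   `labels` and `lobe_map`.
#' @examples
#' m <- default_montage()
#' lobe_channels(m, "parietal")
#' @export
channel_montage <- function(labels, lobe_map) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("duplicate channel labels in montage")
  if (!setequal(names(lobe_map), labels))
    stop("lobe_map must cover every montage label exactly once")
  lobes <- unique(unname(lobe_map))
  structure(list(labels = labels, lobe_map = lobe_map[labels],
                 lobes = lobes),
            class = "channel_montage")
}

#' @rdname channel_montage
#' @export
default_montage <- function() {
  groups <- list(
    frontal   = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
    central   = c("C3", "C4", "Cz"),
    temporal  = c("T3", "T4", "T5", "T6"),
    parietal  = c("P3", "P4", "Pz"),
    occipital = c("O1", "O2")
  )
  # recording order of the 19 sites
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  lobe_map <- stats::setNames(rep(names(groups), lengths(groups)),
                              unlist(groups))
  channel_montage(labels, lobe_map)
}

#' @rdname channel_montage
#' @param montage A `channel_montage`.
#' @param lobe Lobe name.
#' @export
lobe_channels <- function(montage, lobe) {
  stopifnot(inherits(montage, "channel_montage"))
  if (!lobe %in% montage$lobes)
    stop("unknown lobe: ", lobe)
  montage$labels[montage$lobe_map[montage$labels] == lobe]
}

#' Canonical EEG frequency bands
#'
#' Default band edges: delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-30 Hz.  Bands are half-open intervals `[f_low, f_high)`: a
#' spectral bin belongs to a band iff its centre frequency is at or above
#' `f_low` and strictly below `f_high`, so shared edges (8 Hz, 13 Hz) are
#' never double-counted.
#'
#' @return A data.frame with columns `band`, `f_low`, `f_high`.
#' @export
default_bands <- function() {
  data.frame(band   = c("delta", "theta", "alpha", "beta"),
             f_low  = c(0.5, 4, 8, 13),
             f_high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("band", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low >= bands$f_high))
    stop("band f_low must be < f_high")
  b <- bands[order(bands$f_low), ]
  if (nrow(b) > 1 && any(b$f_high[-nrow(b)] > b$f_low[-1] + 1e-12))
    stop("bands must be disjoint")
  invisible(bands)
}
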