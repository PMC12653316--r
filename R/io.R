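#' Write / read EEG recordings as delimited text matrices
#'
#' The on-disk format is a tab-separated matrix, rows = samples, columns =
#' channels, header = 10-20 channel labels, values in microvolts.  A
#' sidecar comment line (`# fs=<Hz> subject=<id> condition=<EO|EC>
#' trial_length=<s>`) carries the recording parameters.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject=%s condition=%s trial_length=%s",
                     rec$sampling_rate, rec$subject_id, rec$condition,
                     if (is.null(rec$trial_length)) "NA"
                     else format(rec$trial_length)), con)
  utils::write.table(format(rec$signal, digits = 8, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg
#' @param path File to read.
#' @param montage Target montage; file labels are matched
#'   case-insensitively, extra channels are dropped with a warning, and a
#'   missing montage channel is an error naming it.
#' @param sampling_rate,subject_id,condition,trial_length Overrides for
#'   files without the sidecar header line.
#' @export
read_eeg <- function(path, montage = default_montage(),
                     sampling_rate = NULL, subject_id = NULL,
                     condition = NULL, trial_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    for (kv in strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  fs <- sampling_rate %||% as.numeric(meta$fs %||% stop(
    "sampling rate not in file header; pass sampling_rate="))
  sid <- subject_id %||% meta$subject %||% "S000"
  cond <- condition %||% meta$condition %||% "EO"
  tl <- trial_length %||%
    (if (!is.null(meta$trial_length) && meta$trial_length != "NA")
       as.numeric(meta$trial_length) else NULL)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", check.names = FALSE)
  labels_file <- names(x)
  matched <- match(tolower(montage$labels), tolower(labels_file))
  if (anyNA(matched)) {
    missing <- montage$labels[is.na(matched)]
    stop("channel(s) missing from file: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(seq_along(labels_file), matched)
  if (length(extra))
    warning("dropping channel(s) not in montage: ",
            paste(labels_file[extra], collapse = ", "))
  eeg_recording(as.matrix(x[, matched]), fs, montage, sid, cond,
                trial_length = tl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to disk
#'
#' One delimited recording file per subject x condition
#' (`<subject>_<condition>.tsv`) plus `metadata.csv`.
#'
#' @param cohort Output of [simulate_cohort()], or a list with `metadata`
#'   and `recordings`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  meta_path <- file.path(out_dir, "metadata.csv")
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE)
  paths <- c(paths, meta_path)
  for (sid in names(cohort$recordings)) {
    for (cond in names(cohort$recordings[[sid]])) {
      p <- file.path(out_dir, sprintf("%s_%s.tsv", sid, cond))
      write_eeg(cohort$recordings[[sid]][[cond]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read cohort metadata
#'
#' @param path `metadata.csv` with columns `subject_id`, `age`, `sex`,
#'   `education_years`, `kmmse`, `oab` (ng/mL).
#' @return data.frame of subject records.
#' @export
read_metadata <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "education_years", "kmmse", "oab")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  m
}
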