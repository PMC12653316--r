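#' Pipeline configuration
#'
#' One structured configuration for a full run, bundling the simulation (or
#' input-directory), preprocessing, spectral and statistical parameters.
#' Every acquisition and analysis constant is a named key with the study
#' default: 250 Hz sampling, ten 30 s trials per condition, 4 s epochs,
#' 0.5-100 Hz band, 2 s / 50% Welch windows, canonical bands, five lobes,
#' 0.78 ng/mL cutoff, covariates age + education + K-MMSE, education strata
#' at 6 and 12 years.
#'
#' @param sim A [sim_config()] (used when `input_dir` is NULL).
#' @param input_dir Optional directory of recordings (`*_EO.tsv`,
#'   `*_EC.tsv`) plus `metadata.csv`; when given, simulation is skipped.
#' @param preprocess A [preprocess_config()].
#' @param analysis An [analysis_config()].
#' @param conditions Conditions to process (default EO and EC).
#' @param window_length,overlap Welch parameters.
#' @param normalization_range Relative-power normalisation range, Hz.
#' @param log_base `"log10"` or `"ln"` for the ratio transform.
#' @param per_channel_ratios Sensitivity switch: average per-channel ratios
#'   instead of forming the ratio of lobar mean powers.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            preprocess = preprocess_config(),
                            analysis = analysis_config(),
                            conditions = c("EO", "EC"),
                            window_length = 2, overlap = 0.5,
                            normalization_range = c(0.5, 100),
                            log_base = "log10",
                            per_channel_ratios = FALSE) {
  structure(list(sim = sim, input_dir = input_dir, preprocess = preprocess,
                 analysis = analysis, conditions = conditions,
                 window_length = window_length, overlap = overlap,
                 normalization_range = normalization_range,
                 log_base = log_base,
                 per_channel_ratios = per_channel_ratios),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()], [sim_config()],
#' [preprocess_config()] and [analysis_config()]; omitted keys keep the
#' study defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's `sim$seed`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(seed)) sim_args$seed <- seed
  args <- list(sim = do.call(sim_config, sim_args),
               preprocess = do.call(preprocess_config, y$preprocess %||% list()),
               analysis = do.call(analysis_config, y$analysis %||% list()))
  for (k in c("input_dir", "conditions", "window_length", "overlap",
              "normalization_range", "log_base", "per_channel_ratios"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Run the full qEEG association pipeline
#'
#' For every subject and condition: obtain the recording (simulated from
#' the planted-model generator, or read from `input_dir`), preprocess
#' (average reference, zero-phase bandpass, epoching, peak-to-peak
#' rejection, minimum-clean-data rule), estimate Welch spectra, form lobar
#' TAR/TBR ratio records; then produce the statistical report: group
#' comparisons with Cohen's d, correlations, unadjusted/adjusted regression
#' models, and education-stratified models.  Subjects failing the retention
#' rule are logged and omitted from that condition, not from the other.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Optional output directory; when given, all report tables,
#'   the rejection log and the run manifest are written as TSV/JSON.
#' @return List of class `pipeline_result`: `ratio_records`, `metadata`,
#'   `rejection_log`, `tables` (group_comparison, correlations,
#'   regressions, stratified), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  simulated <- is.null(config$input_dir)
  metadata <- if (simulated) simulate_metadata(config$sim)
              else read_metadata(file.path(config$input_dir, "metadata.csv"))

  records <- list(); rejlog <- list()
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$subject_id[i]
    for (cond in config$conditions) {
      rec <- if (simulated) {
        simulate_recording(metadata[i, ], cond, config$sim)
      } else {
        path <- file.path(config$input_dir, sprintf("%s_%s.tsv", sid, cond))
        read_eeg(path, subject_id = sid, condition = cond)
      }
      es <- tryCatch(preprocess_recording(rec, config$preprocess),
                     error = function(e)
                       stop("stage preprocess failed for ", sid, "/", cond,
                            ": ", conditionMessage(e)))
      excluded <- is_excluded(es)
      rejlog[[length(rejlog) + 1]] <- data.frame(
        subject_id = sid, condition = cond,
        epochs_total = if (excluded) es$epochs_total else dim(es$epochs)[1],
        epochs_retained = if (excluded) es$epochs_retained
                          else sum(es$retained),
        excluded_flag = excluded, stringsAsFactors = FALSE)
      if (excluded) next
      records[[length(records) + 1]] <-
        lobar_ratios(es, normalization_range = config$normalization_range,
                     window_length = config$window_length,
                     overlap = config$overlap, log_base = config$log_base,
                     per_channel_ratios = config$per_channel_ratios)
    }
  }
  if (!length(records)) stop("all subjects excluded; no data to analyse")
  ratio_records <- do.call(rbind, records)
  rejection_log <- do.call(rbind, rejlog)

  tables <- list(
    group_comparison = do.call(rbind, lapply(
      c(config$conditions, "pooled"), function(cond)
        group_comparison(ratio_records, metadata, config$analysis, cond))),
    correlations = correlation_table(ratio_records, metadata,
                                     config$conditions),
    regressions = regression_table(ratio_records, metadata, config$analysis,
                                   config$conditions),
    stratified = stratified_regression_table(ratio_records, metadata,
                                             config$analysis,
                                             config$conditions))

  manifest <- list(package_version =
                     as.character(utils::packageVersion("qeegratios")),
                   seed = if (simulated) config$sim$seed else NA,
                   source = if (simulated) "simulated" else config$input_dir,
                   n_subjects = nrow(metadata),
                   conditions = config$conditions,
                   excluded = rejection_log[rejection_log$excluded_flag, ,
                                            drop = FALSE],
                   config = config_echo(config))
  result <- structure(list(ratio_records = ratio_records,
                           metadata = metadata,
                           rejection_log = rejection_log,
                           tables = tables, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

config_echo <- function(config) {
  flatten <- function(x) {
    if (inherits(x, c("sim_config", "preprocess_config", "analysis_config",
                      "pipeline_config")))
      x <- unclass(x)
    if (is.list(x)) lapply(x, flatten) else x
  }
  flatten(config)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the ratio records and the four report tables as TSV, the rejection
#' log as TSV, and the manifest (config echo, seed, versions, exclusions,
#' output checksums) as JSON.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wt(result$ratio_records, "ratio_records.tsv"),
             wt(result$rejection_log, "rejection_log.tsv"),
             wt(result$tables$group_comparison, "table_group_comparison.tsv"),
             wt(result$tables$correlations, "table_correlations.tsv"),
             wt(result$tables$regressions, "table_regressions.tsv"),
             wt(result$tables$stratified, "table_stratified.tsv"))
  manifest <- result$manifest
  manifest$output_checksums <- as.list(tools::md5sum(paths))
  names(manifest$output_checksums) <- basename(paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(paths, mp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d subjects, %d ratio records, %d excluded\n",
    nrow(x$metadata), nrow(x$ratio_records),
    sum(x$rejection_log$excluded_flag)))
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
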