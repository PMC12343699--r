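# Plain-CSV dialects and the YAML configuration round-trip.
#
# Series CSV: header `time_min,permittivity_pF_cm`, one row per sample,
# uniform grid. Annotation CSV: `start_min,end_min,label`. Run output CSV:
# `time_min,raw,smoothed,corrected,perm_d,threshold_lower,threshold_upper,
# anomaly_flag,fc_total`. Anomaly matrix CSV: `start_min,end_min`.
# Numeric output uses a fixed significant-digit format so repeated runs
# are byte-identical.

.fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

.write_formatted_csv <- function(df, path, digits = 6L) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]], digits)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a permittivity series CSV
#'
#' Expects the header `time_min,permittivity_pF_cm` and a uniform time
#' grid (strict 60 s cadence by default in the rest of the pipeline).
#' Missing samples are an error unless `gap_fill` is enabled in the
#' pipeline configuration.
#'
#' @param path File path.
#' @return A tibble with columns `time_min` and `permittivity_pF_cm`.
#' @export
read_permittivity_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_min", "permittivity_pF_cm") %in% names(d))) {
    abort("expected header `time_min,permittivity_pF_cm`.",
          class = "permclean_input_error")
  }
  as_tibble(d[, c("time_min", "permittivity_pF_cm")])
}

#' Write a permittivity series CSV
#'
#' @param data A data frame with `time_min` and `permittivity_pF_cm`.
#' @param path File path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return The path, invisibly.
#' @export
write_permittivity_csv <- function(data, path, digits = 6L) {
  .check_series_frame(data)
  .write_formatted_csv(data[, c("time_min", "permittivity_pF_cm")],
                       path, digits)
}

#' Read an annotation CSV (`start_min,end_min,label`)
#'
#' @param path File path.
#' @return A tibble with columns `start_min`, `end_min`, `label`.
#' @export
read_annotations_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("start_min", "end_min") %in% names(d))) {
    abort("expected header `start_min,end_min[,label]`.",
          class = "permclean_input_error")
  }
  if (is.null(d$label)) d$label <- "any"
  as_tibble(d[, c("start_min", "end_min", "label")])
}

#' Write an annotation CSV
#'
#' @param annotations A data frame with `start_min`, `end_min` and
#'   optionally `label`.
#' @param path File path.
#' @param digits Significant digits (default 6).
#' @return The path, invisibly.
#' @export
write_annotations_csv <- function(annotations, path, digits = 6L) {
  if (!all(c("start_min", "end_min") %in% names(annotations))) {
    abort("`annotations` must have `start_min` and `end_min` columns.",
          class = "permclean_input_error")
  }
  keep <- intersect(c("start_min", "end_min", "label"), names(annotations))
  .write_formatted_csv(annotations[, keep], path, digits)
}

#' Write the per-sample output and anomaly matrix of a run
#'
#' @param run An `anomaly_run` from [run_pipeline()].
#' @param output_path CSV path for the per-sample records.
#' @param anomalies_path Optional CSV path for the anomaly matrix
#'   (`start_min,end_min`).
#' @param digits Significant digits (default 6).
#' @return `output_path`, invisibly.
#' @export
write_run_outputs <- function(run, output_path, anomalies_path = NULL,
                              digits = 6L) {
  stopifnot(inherits(run, "anomaly_run"))
  .write_formatted_csv(
    run$data[, c("time_min", "raw", "smoothed", "corrected", "perm_d",
                 "threshold_lower", "threshold_upper", "anomaly_flag",
                 "fc_total")],
    output_path, digits)
  if (!is.null(anomalies_path)) {
    .write_formatted_csv(run$anomalies[, c("start_min", "end_min")],
                         anomalies_path, digits)
  }
  invisible(output_path)
}

#' Serialize a pipeline configuration to YAML
#'
#' The configuration round-trips losslessly through
#' [read_pipeline_config()].
#'
#' @param config A [pipeline_config()].
#' @param path File path for the YAML document.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    smoother = unclass(config$smoother),
    dra = unclass(config$dra),
    threshold = unclass(config$threshold),
    validation_len = config$validation_len,
    replacement_n = config$replacement_n,
    sample_period_s = config$sample_period_s,
    warmup = config$warmup,
    gap_fill = config$gap_fill
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path File path of a YAML document written by
#'   [write_pipeline_config()] (missing fields fall back to defaults).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sm <- do.call(smoother_spec, x$smoother %||% list())
  dra <- do.call(dra_spec, x$dra %||% list())
  thr_args <- x$threshold %||% list()
  thr <- do.call(threshold_spec, thr_args)
  pipeline_config(
    smoother = sm, dra = dra, threshold = thr,
    validation_len = x$validation_len %||% 15L,
    replacement_n = x$replacement_n %||% 15L,
    sample_period_s = x$sample_period_s %||% 60,
    warmup = x$warmup,
    gap_fill = x$gap_fill %||% FALSE
  )
}
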