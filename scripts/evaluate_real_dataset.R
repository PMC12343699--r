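#!/usr/bin/env Rscript
# Optional: score the reference operating point on a real cultivation
# dataset. Not used by the automated checks, which run on synthetic data
# only; supply your own recorded series and manual annotations.
#
# Usage:
#   Rscript scripts/evaluate_real_dataset.R --manifest manifest.csv \
#       [--out report.csv]
#
# The manifest is a CSV with columns `series,annotations`: one row per
# experiment, each pointing to a `time_min,permittivity_pF_cm` series CSV
# and a `start_min,end_min[,label]` annotation CSV (leave `annotations`
# empty for experiments without annotated anomalies; they are omitted
# from F1 averaging but audited for false positives).

suppressPackageStartupMessages(library(permclean))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i)) args[[i[[1L]] + 1L]] else default
}
manifest_path <- get_arg("--manifest")
if (is.null(manifest_path)) stop("--manifest is required")
out_path <- get_arg("--out")

manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
cfg <- pipeline_config()

rows <- lapply(seq_len(nrow(manifest)), function(i) {
  series <- read_permittivity_csv(manifest$series[i])
  ann <- if (!is.na(manifest$annotations[i]) &&
             nzchar(manifest$annotations[i])) {
    read_annotations_csv(manifest$annotations[i])
  } else {
    tibble::tibble(start_min = numeric(0), end_min = numeric(0),
                   label = character(0))
  }
  run <- run_pipeline(series, cfg)
  ref <- smooth_offline(series, span_fraction = 0.03,
                        degree = 2)$reference_pF_cm
  rep <- evaluate_run(run, ann, reference = ref)
  rep$nrmse_raw <- nrmse(ref, series$permittivity_pF_cm)
  rep$experiment <- i
  rep
})
report <- dplyr::bind_rows(rows)

scored <- report[report$annotated, ]
cat(sprintf("experiments: %d (%d with annotated anomalies)\n",
            nrow(report), nrow(scored)))
if (nrow(scored)) {
  cat(sprintf("mean F1 at the default operating point: %.4f\n",
              mean(scored$f1)))
  cat(sprintf("mean precision %.4f, mean recall %.4f\n",
              mean(scored$precision), mean(scored$recall)))
}
cat(sprintf("mean NRMSE: raw %.2f%%, corrected %.2f%%\n",
            mean(report$nrmse_raw), mean(report$nrmse)))
cat(sprintf("mean estimated smoothing delay: %.1f min\n",
            mean(report$delay, na.rm = TRUE)))
if (!is.null(out_path)) readr::write_csv(report, out_path)
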