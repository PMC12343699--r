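# Evaluation machinery: NRMSE against a noiseless reference,
# cross-correlation delay estimation, point-wise confusion metrics against
# annotated anomaly intervals, and parameter grid search.

#' Normalized root mean square error (percent)
#'
#' `100 * sqrt(mean((reference - candidate)^2)) / (max(ref) - min(ref))`:
#' the RMS deviation from the reference, normalized by the reference's
#' range. Used to score smoothed or corrected signals against a noiseless
#' reference.
#'
#' @param reference Reference series (must not be constant).
#' @param candidate Candidate series of equal length.
#'
#' @return NRMSE in percent.
#' @export
#' @examples
#' nrmse(c(0, 2), c(0, 0)) # 70.71
nrmse <- function(reference, candidate) {
  reference <- as.numeric(reference)
  candidate <- as.numeric(candidate)
  if (length(reference) != length(candidate)) {
    abort("`reference` and `candidate` must have equal length.",
          class = "permclean_input_error")
  }
  if (length(reference) < 2L) {
    abort("series must have at least 2 samples.",
          class = "permclean_input_error")
  }
  rng <- max(reference) - min(reference)
  if (rng <= 0) {
    abort("constant reference: range normalization undefined.",
          class = "permclean_input_error")
  }
  100 * sqrt(mean((reference - candidate)^2)) / rng
}

#' Point-wise detection confusion metrics
#'
#' Compares a detected anomaly mask against an annotated mask sample by
#' sample (anomalous data points, not events) and reports TP/FP/FN counts
#' with precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`; 0/0 cases yield 0.
#'
#' @param detected Logical vector of detected flags.
#' @param annotated Logical vector of ground-truth flags, same length.
#'
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
#' @examples
#' anomaly_confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
anomaly_confusion <- function(detected, annotated) {
  detected <- as.logical(detected)
  annotated <- as.logical(annotated)
  if (length(detected) != length(annotated)) {
    abort("masks must have equal length.", class = "permclean_input_error")
  }
  tp <- sum(detected & annotated)
  fp <- sum(detected & !annotated)
  fn <- sum(!detected & annotated)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Convert anomaly intervals to a per-sample mask
#'
#' @param intervals A data frame with `start` and `end` columns (1-based
#'   sample indices, inclusive) or `start_min`/`end_min` together with
#'   `time_min`.
#' @param n Series length, or a `time_min` grid when the intervals are in
#'   minutes.
#'
#' @return A logical vector of length `n` (or `length(time_min)`).
#' @export
intervals_to_mask <- function(intervals, n) {
  if (length(n) > 1L) {
    time_min <- n
    n_len <- length(time_min)
    if (!all(c("start_min", "end_min") %in% names(intervals))) {
      abort("expected `start_min`/`end_min` columns for a time grid.",
            class = "permclean_input_error")
    }
    start <- vapply(intervals$start_min,
                    function(s) which.min(abs(time_min - s)), integer(1))
    end <- vapply(intervals$end_min,
                  function(e) which.min(abs(time_min - e)), integer(1))
  } else {
    n_len <- n
    if (!all(c("start", "end") %in% names(intervals))) {
      abort("expected `start`/`end` index columns.",
            class = "permclean_input_error")
    }
    start <- intervals$start
    end <- intervals$end
  }
  mask <- logical(n_len)
  for (i in seq_along(start)) {
    lo <- max(1L, as.integer(start[i]))
    hi <- min(n_len, as.integer(end[i]))
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}

#' Estimate the delay between two series by cross-correlation
#'
#' Both series are mean-removed; for each candidate lag the Pearson
#' correlation is computed over the overlapping support only, and the lag
#' maximizing it is returned. A positive result means `y` lags behind
#' (is a delayed copy of) `x`. Ties are broken toward the smallest
#' absolute lag.
#'
#' @param x,y Equal-length numeric series.
#' @param max_lag Largest lag magnitude considered, in samples.
#'
#' @return An integer lag in `[-max_lag, max_lag]`.
#' @export
#' @examples
#' x <- cumsum(rnorm(200))
#' estimate_delay(x, c(rep(x[1], 5), head(x, -5)), max_lag = 20) # 5
estimate_delay <- function(x, y, max_lag) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.",
          class = "permclean_input_error")
  }
  max_lag <- .assert_count(max_lag, "max_lag", 0L)
  if (max_lag >= n) {
    abort("`max_lag` must be smaller than the series length.",
          class = "permclean_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance input: correlation undefined.",
          class = "permclean_input_error")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  lags <- -max_lag:max_lag
  lags <- lags[order(abs(lags), lags)]  # smallest |lag| first for ties
  best_lag <- 0L
  best_r <- -Inf
  for (k in lags) {
    # y delayed by k relative to x: compare x[i] with y[i + k]
    if (k >= 0) {
      xi <- xc[seq_len(n - k)]
      yi <- yc[seq_len(n - k) + k]
    } else {
      xi <- xc[seq_len(n + k) - k]
      yi <- yc[seq_len(n + k)]
    }
    sx <- sqrt(sum(xi^2)); sy <- sqrt(sum(yi^2))
    if (sx == 0 || sy == 0) next
    r <- sum(xi * yi) / (sx * sy)
    if (r > best_r + 1e-12) {
      best_r <- r
      best_lag <- k
    }
  }
  as.integer(best_lag)
}

#' Evaluate a pipeline run against annotations
#'
#' Computes the point-wise confusion metrics of the run's anomaly flags
#' against annotated intervals, plus (optionally) the NRMSE of the
#' corrected signal against a noiseless reference and the raw-to-smoothed
#' delay estimate. Series with no annotated anomalies get `NA` metrics
#' (they are omitted from F1 averaging, but their false positives are
#' still counted).
#'
#' @param run An `anomaly_run`, or a data frame with `anomaly_flag` (and
#'   `time_min`) columns.
#' @param annotations A data frame of intervals (`start`/`end` indices or
#'   `start_min`/`end_min`), e.g. from [generate_scenario()].
#' @param reference Optional noiseless reference series (numeric, equal
#'   length) for NRMSE of the corrected signal.
#' @param max_lag Largest lag for the delay estimate (default 60).
#'
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `nrmse`, `delay`, `annotated` (whether any ground-truth
#'   anomalies exist).
#' @export
evaluate_run <- function(run, annotations, reference = NULL, max_lag = 60L) {
  d <- if (inherits(run, "anomaly_run")) run$data else as_tibble(run)
  if (!"anomaly_flag" %in% names(d)) {
    abort("`run` must carry an `anomaly_flag` column.",
          class = "permclean_input_error")
  }
  n <- nrow(d)
  mask <- if (all(c("start_min", "end_min") %in% names(annotations)) &&
              "time_min" %in% names(d)) {
    intervals_to_mask(annotations, d$time_min)
  } else {
    intervals_to_mask(annotations, n)
  }
  annotated <- any(mask)
  conf <- anomaly_confusion(d$anomaly_flag, mask)
  if (!annotated) {
    conf$precision <- NA_real_; conf$recall <- NA_real_; conf$f1 <- NA_real_
  }
  nr <- if (!is.null(reference)) {
    nrmse(as.numeric(reference), d$corrected)
  } else {
    NA_real_
  }
  delay <- if (all(c("raw", "smoothed") %in% names(d)) &&
               !anyNA(d$smoothed) && sd(d$raw) > 0) {
    estimate_delay(d$raw, d$smoothed, max_lag)
  } else {
    NA_integer_
  }
  dplyr::bind_cols(conf, tibble(nrmse = nr, delay = delay,
                                annotated = annotated))
}

#' Grid search over pipeline parameters
#'
#' Runs the full pipeline for every parameter combination in `grid` over a
#' suite of annotated datasets and ranks the combinations by mean F1
#' across the datasets that contain annotated anomalies (datasets without
#' any are excluded from the average, but their false positives are
#' reported in a diagnostic column). Ties are broken by smaller `w2`,
#' then smaller static threshold.
#'
#' @param datasets A list whose elements are `perm_scenario` objects or
#'   lists with elements `signal` (series tibble) and `annotations`.
#' @param grid A data frame of parameter columns; recognized names:
#'   `static_value`, `threshold_factor`, `kind`, `w3`, `w1`, `w2`, `mode`,
#'   `smoother_method`, `smoother_w`. Unrecognized columns raise an error.
#' @param config_base A [pipeline_config()] supplying everything the grid
#'   does not vary.
#'
#' @return A tibble with one row per grid point: the grid columns plus
#'   `mean_precision`, `mean_recall`, `mean_f1`, `fp_unannotated` and
#'   `n_datasets`, sorted by decreasing `mean_f1`.
#' @export
grid_search <- function(datasets, grid, config_base = pipeline_config()) {
  if (length(datasets) == 0L) {
    abort("`datasets` must be nonempty.", class = "permclean_input_error")
  }
  grid <- as_tibble(grid)
  if (nrow(grid) == 0L) {
    abort("`grid` must be nonempty.", class = "permclean_input_error")
  }
  known <- c("static_value", "threshold_factor", "kind", "w3", "w1", "w2",
             "mode", "smoother_method", "smoother_w")
  bad <- setdiff(names(grid), known)
  if (length(bad)) {
    abort(paste0("unrecognized grid columns: ",
                 paste(bad, collapse = ", ")),
          class = "permclean_parameter_error")
  }
  dsets <- lapply(datasets, function(ds) {
    if (inherits(ds, "perm_scenario")) {
      list(signal = ds$signal, annotations = ds$annotations)
    } else {
      stopifnot(is.list(ds), !is.null(ds$signal), !is.null(ds$annotations))
      ds
    }
  })
  masks <- lapply(dsets, function(ds) {
    if (all(c("start_min", "end_min") %in% names(ds$annotations))) {
      intervals_to_mask(ds$annotations, ds$signal$time_min)
    } else {
      intervals_to_mask(ds$annotations, nrow(ds$signal))
    }
  })
  annotated <- vapply(masks, any, logical(1))
  if (!any(annotated)) {
    abort("all datasets are anomaly-free: F1 is undefined.",
          class = "permclean_input_error")
  }

  results <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    row <- grid[g, , drop = FALSE]
    cfg <- .apply_grid_row(config_base, row)
    prec <- c(); rec <- c(); f1 <- c(); fp_un <- 0L
    for (j in seq_along(dsets)) {
      run <- run_pipeline(dsets[[j]]$signal, cfg)
      conf <- anomaly_confusion(run$data$anomaly_flag, masks[[j]])
      if (annotated[j]) {
        prec <- c(prec, conf$precision)
        rec <- c(rec, conf$recall)
        f1 <- c(f1, conf$f1)
      } else {
        fp_un <- fp_un + conf$fp
      }
    }
    dplyr::bind_cols(row, tibble(
      mean_precision = mean(prec), mean_recall = mean(rec),
      mean_f1 = mean(f1), fp_unannotated = fp_un,
      n_datasets = sum(annotated)
    ))
  })
  sort_cols <- list(dplyr::desc(results$mean_f1))
  if ("w2" %in% names(results)) sort_cols <- c(sort_cols, list(results$w2))
  if ("static_value" %in% names(results)) {
    sort_cols <- c(sort_cols, list(results$static_value))
  }
  results[do.call(order, sort_cols), , drop = FALSE]
}

.apply_grid_row <- function(config, row) {
  gv <- function(nm) if (nm %in% names(row)) row[[nm]] else NULL
  sm <- config$smoother
  dra <- config$dra
  thr <- config$threshold
  if (!is.null(gv("smoother_method")) || !is.null(gv("smoother_w"))) {
    sm <- smoother_spec(
      method = gv("smoother_method") %||% sm$method,
      w = gv("smoother_w") %||% sm$w,
      poly_degree = sm$poly_degree,
      robust_iterations = sm$robust_iterations
    )
  }
  if (!is.null(gv("w1")) || !is.null(gv("w2")) || !is.null(gv("mode"))) {
    dra <- dra_spec(w1 = gv("w1") %||% dra$w1, w2 = gv("w2") %||% dra$w2,
                    mode = gv("mode") %||% dra$mode)
  }
  if (!is.null(gv("kind")) || !is.null(gv("static_value")) ||
      !is.null(gv("threshold_factor")) || !is.null(gv("w3"))) {
    kind <- as.character(gv("kind") %||% thr$kind)
    thr <- threshold_spec(
      kind = kind,
      static_value = gv("static_value") %||% thr$static_value,
      threshold_factor = gv("threshold_factor") %||%
        (if (kind == thr$kind) thr$threshold_factor else NULL),
      b_constant = thr$b_constant,
      w3 = gv("w3") %||% thr$w3,
      two_sided = thr$two_sided,
      min_scale = thr$min_scale
    )
  }
  pipeline_config(
    smoother = sm, dra = dra, threshold = thr,
    validation_len = config$validation_len,
    replacement_n = config$replacement_n,
    sample_period_s = config$sample_period_s,
    gap_fill = config$gap_fill
  )
}
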