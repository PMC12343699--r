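# Parameter objects for the smoothing / DRA / detection stages and the
# full pipeline. All constructors validate eagerly and return small classed
# lists so that a misconfiguration fails at build time, not mid-stream.

.assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(lower)),
          class = "permclean_parameter_error")
  }
  invisible(x)
}

.assert_count <- function(x, name, lower = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= lower && x == as.integer(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower),
          class = "permclean_parameter_error")
  }
  as.integer(x)
}

#' Specify a signal smoother
#'
#' Describes both the offline reference smoothers and the causal (streaming)
#' noise filters. The window `w` is the number of samples the filter looks
#' at; in streaming use the window is right-aligned, ending at the newest
#' sample, so the theoretical group delay is `(w - 1) / 2` samples (see
#' [theoretical_delay()]).
#'
#' @param method One of `"gaussian"`, `"moving_mean"`, `"moving_median"`,
#'   `"savitzky_golay"`, `"lowess"` (local linear) or `"loess"` (local
#'   quadratic).
#' @param w Window length in samples (integer >= 1). Default 70, the
#'   operating point used for the Gaussian filter in the reference workflow.
#' @param gaussian_sigma Standard deviation of the Gaussian weight kernel,
#'   in samples. Defaults to `w / 5`.
#' @param poly_degree Polynomial degree for the Savitzky-Golay filter
#'   (default 2). Requires `w >= poly_degree + 1`.
#' @param robust_iterations Number of bisquare reweighting passes for the
#'   local-regression methods; 0 (default) means a plain weighted fit.
#'
#' @return An object of class `smoother_spec`.
#' @export
#' @examples
#' smoother_spec("gaussian", w = 70)
#' smoother_spec("moving_median", w = 5)
smoother_spec <- function(method = c("gaussian", "moving_mean", "moving_median",
                                     "savitzky_golay", "lowess", "loess"),
                          w = 70L,
                          gaussian_sigma = NULL,
                          poly_degree = 2L,
                          robust_iterations = 0L) {
  method <- match.arg(method)
  w <- .assert_count(w, "w", 1L)
  poly_degree <- .assert_count(poly_degree, "poly_degree", 0L)
  robust_iterations <- .assert_count(robust_iterations, "robust_iterations", 0L)
  if (method == "savitzky_golay" && w < poly_degree + 1L) {
    abort("Savitzky-Golay requires `w >= poly_degree + 1`.",
          class = "permclean_parameter_error")
  }
  if (is.null(gaussian_sigma)) gaussian_sigma <- w / 5
  .assert_number(gaussian_sigma, "gaussian_sigma", 0, strict = TRUE)
  structure(
    list(method = method, w = w, gaussian_sigma = gaussian_sigma,
         poly_degree = poly_degree, robust_iterations = robust_iterations),
    class = "smoother_spec"
  )
}

#' Specify a double rolling aggregate (DRA) transform
#'
#' The DRA subtracts the aggregates of two co-moving windows to strip the
#' local signal level (context) and expose sudden changes. In
#' `"overlapping"` mode both windows end at the current sample; in
#' `"adjacent"` mode the `w2` window immediately precedes the `w1` window.
#' The transformed value is (short/recent aggregate) minus (long aggregate),
#' so a sudden upward jump produces a positive value.
#'
#' @param w1 Length of the recent window, in samples (>= 1). Default 1.
#' @param w2 Length of the context window, in samples (>= 1). Default 15.
#' @param mode `"overlapping"` (default) or `"adjacent"`.
#' @param aggregate Aggregation function; only `"mean"` is currently
#'   supported.
#'
#' @return An object of class `dra_spec`.
#' @export
#' @examples
#' dra_spec(w1 = 1, w2 = 15)
dra_spec <- function(w1 = 1L, w2 = 15L,
                     mode = c("overlapping", "adjacent"),
                     aggregate = "mean") {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  structure(
    list(w1 = .assert_count(w1, "w1", 1L), w2 = .assert_count(w2, "w2", 1L),
         mode = mode, aggregate = aggregate),
    class = "dra_spec"
  )
}

#' Specify an anomaly detection threshold
#'
#' A static threshold compares the DRA-transformed signal against a fixed
#' value (default 1.06 pF/cm). The dynamic kinds build a band
#' `location +/- factor * scale` from a rolling window of `w3` past
#' transformed values: `"three_sigma"` uses mean and sample standard
#' deviation (factor 3), `"hampel"` uses median and the MAD scale estimate
#' `b * median(|x - median|)` with `b = 1.4826` under normality, and
#' `"iqr"` uses median and the interquartile range (factor 2, equivalent to
#' roughly +/- 2.7 sigma for normal data).
#'
#' @param kind `"static"`, `"three_sigma"`, `"hampel"` or `"iqr"`.
#' @param static_value Static threshold in pF/cm (default 1.06).
#' @param threshold_factor Dimensionless multiplier of the scale estimate.
#'   Defaults to 3 for `three_sigma` and `hampel`, 2 for `iqr`.
#' @param b_constant Normal-consistency constant of the MAD (default
#'   1.4826).
#' @param w3 Rolling window length for the dynamic kinds (>= 2; >= 4 for
#'   `iqr`).
#' @param two_sided Flag deviations of either sign (default `TRUE`): a
#'   spike has an up- and a down-flank, so both signs carry signal.
#' @param min_scale Floor on the scale estimate, guarding against collapsed
#'   bands on near-constant windows (default 0).
#'
#' @return An object of class `threshold_spec`.
#' @export
#' @examples
#' threshold_spec("static", static_value = 1.06)
#' threshold_spec("hampel", w3 = 20)
threshold_spec <- function(kind = c("static", "three_sigma", "hampel", "iqr"),
                           static_value = 1.06,
                           threshold_factor = NULL,
                           b_constant = 1.4826,
                           w3 = NULL,
                           two_sided = TRUE,
                           min_scale = 0) {
  kind <- match.arg(kind)
  .assert_number(static_value, "static_value", 0, strict = TRUE)
  if (is.null(threshold_factor)) {
    threshold_factor <- if (kind == "iqr") 2 else 3
  }
  .assert_number(threshold_factor, "threshold_factor", 0, strict = TRUE)
  .assert_number(b_constant, "b_constant", 0, strict = TRUE)
  .assert_number(min_scale, "min_scale", 0)
  if (kind != "static") {
    if (is.null(w3)) {
      abort(sprintf("`w3` is required for the dynamic threshold kind \"%s\".",
                    kind),
            class = "permclean_parameter_error")
    }
    w3 <- .assert_count(w3, "w3", if (kind == "iqr") 4L else 2L)
  } else {
    w3 <- NULL
  }
  stopifnot(is.logical(two_sided), length(two_sided) == 1L)
  structure(
    list(kind = kind, static_value = static_value,
         threshold_factor = threshold_factor, b_constant = b_constant,
         w3 = w3, two_sided = two_sided, min_scale = min_scale),
    class = "threshold_spec"
  )
}

#' Assemble a full pipeline configuration
#'
#' Bundles the smoother, the DRA transform and the threshold rule together
#' with the anomaly-handling tunables. The defaults reproduce the reference
#' operating point: Gaussian smoothing with `w = 70`, overlapping DRA with
#' `w1 = 1`, `w2 = 15`, and a static threshold of 1.06 pF/cm, with a
#' 15-sample validation period and a 15-sample replacement window.
#'
#' @param smoother A [smoother_spec()].
#' @param dra A [dra_spec()].
#' @param threshold A [threshold_spec()].
#' @param validation_len Post-anomaly validation period, in samples
#'   (default 15). Anomalies closer together than this are merged.
#' @param replacement_n Window for the replacement mean and the pre/post
#'   level estimates, in samples (default 15).
#' @param sample_period_s Sampling period of the input stream, in seconds
#'   (default 60).
#' @param warmup Number of initial samples during which detection is
#'   suppressed. `NULL` (default) uses the longest configured window.
#' @param gap_fill If `TRUE`, missing samples on the time grid are filled
#'   and treated as sensor dropouts (held at the last corrected level). If
#'   `FALSE` (default), gaps are an error.
#'
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config()
#' pipeline_config(smoother = smoother_spec("moving_mean", w = 1))
pipeline_config <- function(smoother = smoother_spec(),
                            dra = dra_spec(),
                            threshold = threshold_spec("static"),
                            validation_len = 15L,
                            replacement_n = 15L,
                            sample_period_s = 60,
                            warmup = NULL,
                            gap_fill = FALSE) {
  stopifnot(inherits(smoother, "smoother_spec"),
            inherits(dra, "dra_spec"),
            inherits(threshold, "threshold_spec"))
  validation_len <- .assert_count(validation_len, "validation_len", 1L)
  replacement_n <- .assert_count(replacement_n, "replacement_n", 1L)
  .assert_number(sample_period_s, "sample_period_s", 0, strict = TRUE)
  dra_need <- if (dra$mode == "overlapping") max(dra$w1, dra$w2) else
    dra$w1 + dra$w2
  if (is.null(warmup)) {
    warmup <- max(smoother$w, dra_need, replacement_n)
  }
  warmup <- .assert_count(warmup, "warmup", 0L)
  stopifnot(is.logical(gap_fill), length(gap_fill) == 1L)
  structure(
    list(smoother = smoother, dra = dra, threshold = threshold,
         validation_len = validation_len, replacement_n = replacement_n,
         sample_period_s = sample_period_s, warmup = warmup,
         gap_fill = gap_fill),
    class = "pipeline_config"
  )
}

#' @export
print.smoother_spec <- function(x, ...) {
  cat(sprintf("<smoother_spec> %s, w = %d", x$method, x$w))
  if (x$method == "gaussian") cat(sprintf(", sigma = %g", x$gaussian_sigma))
  if (x$method == "savitzky_golay") cat(sprintf(", degree = %d", x$poly_degree))
  if (x$robust_iterations > 0)
    cat(sprintf(", robust iterations = %d", x$robust_iterations))
  cat("\n")
  invisible(x)
}

#' @export
print.dra_spec <- function(x, ...) {
  cat(sprintf("<dra_spec> %s %s, w1 = %d, w2 = %d\n",
              x$mode, x$aggregate, x$w1, x$w2))
  invisible(x)
}

#' @export
print.threshold_spec <- function(x, ...) {
  if (x$kind == "static") {
    cat(sprintf("<threshold_spec> static, value = %g pF/cm, %s\n",
                x$static_value, if (x$two_sided) "two-sided" else "one-sided"))
  } else {
    cat(sprintf("<threshold_spec> %s, factor = %g, w3 = %d, %s\n",
                x$kind, x$threshold_factor, x$w3,
                if (x$two_sided) "two-sided" else "one-sided"))
  }
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  smoother:  "); print(x$smoother)
  cat("  dra:       "); print(x$dra)
  cat("  threshold: "); print(x$threshold)
  cat(sprintf("  validation_len = %d, replacement_n = %d, warmup = %d\n",
              x$validation_len, x$replacement_n, x$warmup))
  cat(sprintf("  sample period = %g s, gap_fill = %s\n",
              x$sample_period_s, x$gap_fill))
  invisible(x)
}
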