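# Offline reference smoothing and causal (streaming) noise filters.
#
# The causal filters consume a right-aligned window ending at the newest
# sample: at time t only samples up to t are used, so the smoothed value at
# t never changes when later samples arrive. During warm-up (fewer than w
# samples seen) the filters use all available samples so the output series
# stays full length.

#' Offline reference smoothing (local polynomial regression)
#'
#' Smooths a complete series with tricube-weighted local polynomial
#' regression (loess) to obtain a "noiseless" reference against which
#' streaming filters can be scored with [nrmse()]. This is an offline
#' operation: it uses the full series, including future samples.
#'
#' @param data A data frame with columns `time_min` and
#'   `permittivity_pF_cm` on a uniform time grid, or a bare numeric vector.
#' @param span_fraction Fraction of the series length used for each local
#'   fit (default 0.03).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @param robust_iterations Number of robustness (iterated reweighting)
#'   passes; 0 (default) is the plain fit.
#'
#' @return For data-frame input, the input tibble with an added
#'   `reference_pF_cm` column; for numeric input, a numeric vector of the
#'   same length.
#' @export
#' @examples
#' y <- sin(seq(0, 4 * pi, length.out = 400)) + rnorm(400, sd = 0.1)
#' ref <- smooth_offline(y, span_fraction = 0.05)
smooth_offline <- function(data, span_fraction = 0.03, degree = 2L,
                           robust_iterations = 0L) {
  .assert_number(span_fraction, "span_fraction", 0, strict = TRUE)
  if (span_fraction > 1) {
    abort("`span_fraction` must be in (0, 1].",
          class = "permclean_parameter_error")
  }
  degree <- .assert_count(degree, "degree", 1L)
  if (degree > 2L) {
    abort("`degree` must be 1 or 2.", class = "permclean_parameter_error")
  }
  robust_iterations <- .assert_count(robust_iterations, "robust_iterations", 0L)

  if (is.data.frame(data)) {
    .check_series_frame(data)
    y <- data$permittivity_pF_cm
    t <- data$time_min
  } else if (is.numeric(data)) {
    y <- as.numeric(data)
    t <- seq_along(y)
  } else {
    abort("`data` must be a data frame or a numeric vector.",
          class = "permclean_input_error")
  }
  n <- length(y)
  if (n < 3L) {
    abort("series must have at least 3 samples.",
          class = "permclean_input_error")
  }
  if (ceiling(span_fraction * n) < degree + 1L) {
    abort(sprintf(
      "span too small: ceiling(span_fraction * n) = %d local points < degree + 1 = %d.",
      ceiling(span_fraction * n), degree + 1L),
      class = "permclean_parameter_error")
  }

  fit <- loess(
    y ~ t, data = data.frame(t = t, y = y),
    span = span_fraction, degree = degree,
    family = if (robust_iterations > 0) "symmetric" else "gaussian",
    control = loess.control(surface = "direct",
                            iterations = robust_iterations + 1L)
  )
  out <- as.numeric(fitted(fit))
  if (is.data.frame(data)) {
    res <- as_tibble(data)
    res$reference_pF_cm <- out
    res
  } else {
    out
  }
}

# Weighted least-squares polynomial fit over times x (newest at x = 0),
# evaluated at x = 0. Degrades gracefully for short buffers.
.polyfit_at_zero <- function(x, y, degree, w = NULL, robust_iterations = 0L) {
  m <- length(y)
  degree <- min(degree, m - 1L)
  if (degree == 0L) {
    if (is.null(w)) return(mean(y))
    return(sum(w * y) / sum(w))
  }
  X <- outer(x, 0:degree, `^`)
  if (is.null(w)) w <- rep(1, m)
  fit <- lm.wfit(X, y, w)
  coefs <- fit$coefficients
  for (i in seq_len(robust_iterations)) {
    res <- y - drop(X %*% ifelse(is.na(coefs), 0, coefs))
    s <- 6 * median(abs(res))
    if (!is.finite(s) || s <= 0) break
    u <- res / s
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(rw * w == 0)) break
    fit <- lm.wfit(X, y, w * rw)
    coefs <- fit$coefficients
  }
  if (is.na(coefs[1L])) mean(y) else unname(coefs[1L])
}

#' Causal one-step smoothing
#'
#' Computes the smoothed value for the newest sample from a buffer of the
#' most recent observations (oldest first). Only the last `spec$w` samples
#' are used; shorter buffers (warm-up) are used in full. The moving mean
#' and median aggregate the window; the Gaussian filter takes a normalized
#' weighted mean with weights from a Gaussian centered on the newest
#' sample; the Savitzky-Golay, lowess and loess variants fit a polynomial
#' over the window and evaluate it at the newest time point.
#'
#' @param buffer Numeric vector of recent values, ordered oldest to newest.
#' @param spec A [smoother_spec()].
#'
#' @return A single smoothed value.
#' @export
#' @examples
#' smooth_causal(c(1, 2, 3), smoother_spec("moving_mean", w = 3))
#' smooth_causal(c(10, 10, 100, 10, 10), smoother_spec("moving_median", w = 5))
smooth_causal <- function(buffer, spec) {
  stopifnot(inherits(spec, "smoother_spec"))
  if (length(buffer) == 0L) {
    abort("empty smoothing buffer.", class = "permclean_state_error")
  }
  b <- tail(as.numeric(buffer), spec$w)
  m <- length(b)
  if (m == 1L) return(b)
  switch(
    spec$method,
    moving_mean = mean(b),
    moving_median = median(b),
    gaussian = {
      age <- (m - 1L):0L
      wts <- exp(-age^2 / (2 * spec$gaussian_sigma^2))
      wts <- wts / sum(wts)
      sum(wts * b)
    },
    savitzky_golay = {
      x <- seq_len(m) - m  # newest sample at x = 0
      .polyfit_at_zero(x, b, spec$poly_degree)
    },
    lowess = ,
    loess = {
      x <- seq_len(m) - m
      u <- (-x) / m  # age scaled to [0, 1); newest weight 1
      wts <- (1 - u^3)^3
      .polyfit_at_zero(x, b, if (spec$method == "lowess") 1L else 2L,
                       w = wts,
                       robust_iterations = spec$robust_iterations)
    }
  )
}

#' Theoretical group delay of a symmetric window filter
#'
#' A window of `w` samples delays the output by `(w - 1) / 2` samples
#' relative to the input, the classic trade-off between noise reduction and
#' latency for streaming filters.
#'
#' @param w Window length(s) in samples (>= 1).
#'
#' @return Delay in samples; fractional for even `w`.
#' @export
#' @examples
#' theoretical_delay(11) # 5
#' theoretical_delay(70) # 34.5
theoretical_delay <- function(w) {
  if (!is.numeric(w) || length(w) < 1L || any(!is.finite(w)) || any(w < 1)) {
    abort("`w` must be numeric with all values >= 1.",
          class = "permclean_parameter_error")
  }
  (w - 1) / 2
}

# Shared input check: a series frame with a uniform time grid.
.check_series_frame <- function(data, require_value = TRUE) {
  if (!all(c("time_min", if (require_value) "permittivity_pF_cm") %in%
           names(data))) {
    abort("series data must have columns `time_min` and `permittivity_pF_cm`.",
          class = "permclean_input_error")
  }
  t <- data$time_min
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(abs(dt - dt[1L]) > 1e-6 * max(abs(dt[1L]), 1))) {
      abort("`time_min` must be a uniform grid.",
            class = "permclean_input_error")
    }
    if (dt[1L] <= 0) {
      abort("`time_min` must be strictly increasing.",
            class = "permclean_input_error")
    }
  }
  invisible(data)
}
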