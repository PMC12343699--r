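# Threshold-based anomaly decision on the DRA-transformed signal.
#
# The static rule compares against a fixed value. The dynamic rules build
# a band (location +/- factor * scale) from a rolling window of *past*
# transformed values, so a jump cannot inflate its own band; the price is
# that a sudden volatility increase raises the band only with a delay.

# Internal band kernels return c(center, lower, upper).
.band_three_sigma <- function(window, factor, min_scale = 0) {
  ctr <- mean(window)
  sc <- max(sd(window), min_scale)
  c(ctr, ctr - factor * sc, ctr + factor * sc)
}

.band_hampel <- function(window, factor, b, min_scale = 0) {
  ctr <- median(window)
  sc <- max(b * median(abs(window - ctr)), min_scale)
  c(ctr, ctr - factor * sc, ctr + factor * sc)
}

.band_iqr <- function(window, factor, min_scale = 0) {
  ctr <- median(window)
  qs <- quantile(window, c(0.25, 0.75), names = FALSE, type = 7)
  sc <- max(qs[2L] - qs[1L], min_scale)
  c(ctr, ctr - factor * sc, ctr + factor * sc)
}

.band_kernel <- function(window, spec) {
  switch(spec$kind,
         three_sigma = .band_three_sigma(window, spec$threshold_factor,
                                         spec$min_scale),
         hampel = .band_hampel(window, spec$threshold_factor,
                               spec$b_constant, spec$min_scale),
         iqr = .band_iqr(window, spec$threshold_factor, spec$min_scale),
         abort("no band for a static threshold.",
               class = "permclean_parameter_error"))
}

.band_tibble <- function(v) tibble(center = v[1L], lower = v[2L], upper = v[3L])

#' 3-sigma threshold band
#'
#' Band `mean +/- factor * sd` over a window, with the sample (n - 1)
#' standard deviation. A zero-variance window collapses the band to the
#' center; detection then flags any strictly nonzero deviation.
#'
#' @param window Numeric window of past transformed values (length >= 2).
#' @param factor Threshold factor (default 3).
#'
#' @return A one-row tibble with columns `center`, `lower`, `upper`.
#' @export
#' @examples
#' band_three_sigma(1:10)
band_three_sigma <- function(window, factor = 3) {
  if (length(window) < 2L) {
    abort("window must have at least 2 values.",
          class = "permclean_parameter_error")
  }
  .band_tibble(.band_three_sigma(as.numeric(window), factor))
}

#' Hampel identifier band
#'
#' Band `median +/- factor * b * MAD`, where `MAD = median(|x - median|)`
#' and `b = 1.4826` makes the MAD a consistent estimate of sigma for
#' normal data. Robust to masking: a single large outlier barely moves the
#' band edges.
#'
#' @param window Numeric window (length >= 2).
#' @param factor Threshold factor (default 3).
#' @param b Normal-consistency constant (default 1.4826).
#'
#' @return A one-row tibble with columns `center`, `lower`, `upper`.
#' @export
#' @examples
#' band_hampel(c(1, 2, 3, 4, 100)) # (-1.4478, 7.4478); 100 lies outside
band_hampel <- function(window, factor = 3, b = 1.4826) {
  if (length(window) < 2L) {
    abort("window must have at least 2 values.",
          class = "permclean_parameter_error")
  }
  .band_tibble(.band_hampel(as.numeric(window), factor, b))
}

#' IQR threshold band
#'
#' Band `median +/- factor * (Q3 - Q1)` with linear-interpolation
#' quantiles (type 7). With the default factor 2 this corresponds to about
#' +/- 2.7 sigma under normality, since IQR / 1.35 is an unbiased estimate
#' of sigma for normal data.
#'
#' @param window Numeric window (length >= 4).
#' @param factor Threshold factor (default 2).
#'
#' @return A one-row tibble with columns `center`, `lower`, `upper`.
#' @export
#' @examples
#' band_iqr(1:5) # center 3, band (-1, 7)
band_iqr <- function(window, factor = 2) {
  if (length(window) < 4L) {
    abort("window must have at least 4 values.",
          class = "permclean_parameter_error")
  }
  .band_tibble(.band_iqr(as.numeric(window), factor))
}

#' Static threshold decision
#'
#' Flags a DRA-transformed value as anomalous when it exceeds the fixed
#' threshold: `|perm_d| > static_value` when two-sided (the default;
#' spikes have flanks of both signs), `perm_d > static_value` otherwise.
#'
#' @param perm_d Transformed value(s) in pF/cm (vectorized).
#' @param spec A [threshold_spec()] with `kind = "static"`.
#'
#' @return Logical vector of anomaly flags.
#' @export
#' @examples
#' static_decide(c(0, 1.07, -1.2), threshold_spec("static"))
static_decide <- function(perm_d, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$kind != "static") {
    abort("`spec` must have kind \"static\".",
          class = "permclean_parameter_error")
  }
  if (spec$two_sided) abs(perm_d) > spec$static_value
  else perm_d > spec$static_value
}

#' Dynamic threshold decision
#'
#' Flags `perm_d` when it falls strictly outside the band computed from
#' the `w3` transformed values immediately preceding it. The window must
#' exclude the current sample, so an incoming jump cannot widen the band
#' that judges it. Strict inequality makes collapsed (zero-scale) bands
#' flag any nonzero deviation rather than everything.
#'
#' @param perm_d The current transformed value.
#' @param window The previous `w3` transformed values.
#' @param spec A [threshold_spec()] with a dynamic kind.
#'
#' @return A single logical flag.
#' @export
#' @examples
#' dynamic_decide(0.5, rep(0, 120), threshold_spec("three_sigma", w3 = 120))
dynamic_decide <- function(perm_d, window, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$kind == "static") {
    abort("`spec` must have a dynamic kind.",
          class = "permclean_parameter_error")
  }
  if (length(window) != spec$w3) {
    abort(sprintf("window must hold exactly w3 = %d past values.", spec$w3),
          class = "permclean_parameter_error")
  }
  band <- .band_kernel(as.numeric(window), spec)
  if (spec$two_sided) {
    perm_d < band[2L] || perm_d > band[3L]
  } else {
    perm_d > band[3L]
  }
}

#' Maximum attainable threshold factor for a window size
#'
#' Within a sample of size `w`, no point can lie more than
#' `(w - 1) / sqrt(w)` sample standard deviations from the sample mean, so
#' a threshold factor above this bound can never fire on in-window points.
#' The bound crosses 3 between `w = 10` (2.846) and `w = 11` (3.015):
#' windows must exceed 10 samples for the 3-sigma rule to be able to
#' detect anything.
#'
#' @param w Window length(s), `>= 2`.
#'
#' @return Dimensionless bound(s), monotone increasing in `w`.
#' @export
#' @examples
#' max_threshold_factor(c(4, 10, 11))
max_threshold_factor <- function(w) {
  if (!is.numeric(w) || length(w) < 1L || any(!is.finite(w)) || any(w < 2)) {
    abort("`w` must be numeric with all values >= 2.",
          class = "permclean_parameter_error")
  }
  (w - 1) / sqrt(w)
}

#' Normal-theory constants behind the threshold rules
#'
#' Recomputes, from the normal distribution itself, the constants the
#' threshold rules rely on: the 3-sigma coverage, the MAD
#' normal-consistency constant `b = 1 / qnorm(3/4)`, the IQR-to-sigma
#' ratio, the sigma-equivalent of the IQR band at factor 2, and the
#' smallest window for which the 3-sigma rule can fire at all (via
#' [max_threshold_factor()]).
#'
#' @return A tibble with columns `constant`, `value`, `printed`
#'   (conventional rounded form) and `description`.
#' @export
#' @examples
#' normal_consistency_constants()
normal_consistency_constants <- function() {
  coverage <- 100 * (2 * pnorm(3) - 1)
  b <- 1 / qnorm(0.75)
  iqr_sigma <- qnorm(0.75) - qnorm(0.25)
  band_sigma <- 2 * iqr_sigma
  w_min <- 2L
  while (max_threshold_factor(w_min) <= 3) w_min <- w_min + 1L
  tibble(
    constant = c("three_sigma_coverage_pct", "hampel_b", "iqr_to_sigma",
                 "iqr_factor2_sigma_band", "min_window_three_sigma"),
    value = c(coverage, b, iqr_sigma, band_sigma, w_min),
    printed = c(99.73, 1.4826, 1.35, 2.7, 11),
    description = c(
      "share of normal data within mean +/- 3 sd (%)",
      "MAD normal-consistency constant b",
      "IQR of a standard normal (sigma units)",
      "half-width of the factor-2 IQR band (sigma units)",
      "smallest window where the max attainable z-score exceeds 3"
    )
  )
}
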