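# Synthetic fed-batch permittivity traces with ground-truth annotations.
#
# The clean trace emulates the qualitative shape of an in-line
# permittivity (viable biomass) signal in a glycerol-batch /
# methanol-fed-batch yeast cultivation: piecewise exponential growth, a
# smooth non-anomalous dip at the substrate switch (the methanol
# adaptation phase), and an optional stationary plateau. Spike and shift
# anomalies are injected on top of seeded Gaussian noise, and the injected
# samples are returned as annotations; the dip is deliberately *not*
# annotated — gradual, process-driven excursions are not sensor anomalies.

#' Describe an anomaly injection
#'
#' @param kind `"spike"` (transient up-then-back excursion) or `"shift"`
#'   (persistent step).
#' @param onset_index 1-based sample index of the first affected sample.
#' @param magnitude Height in pF/cm; must be nonzero.
#' @param width Number of elevated samples for spikes (>= 1, ignored for
#'   shifts).
#'
#' @return An object of class `injection`.
#' @export
#' @examples
#' injection("spike", onset_index = 100, magnitude = 8, width = 5)
injection <- function(kind = c("spike", "shift"), onset_index, magnitude,
                      width = 1L) {
  kind <- match.arg(kind)
  onset_index <- .assert_count(onset_index, "onset_index", 1L)
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      !is.finite(magnitude) || magnitude == 0) {
    abort("`magnitude` must be a single nonzero number.",
          class = "permclean_spec_error")
  }
  width <- .assert_count(width, "width", 1L)
  structure(list(kind = kind, onset_index = onset_index,
                 magnitude = magnitude, width = width),
            class = "injection")
}

#' Apply an injection to a series
#'
#' Spikes add `magnitude` over `[onset, onset + width)` and return to the
#' original values afterwards (zero-sum up-then-down excursion); shifts
#' add `magnitude` from the onset to the end of the series.
#'
#' @param x Numeric series.
#' @param inj An [injection()].
#'
#' @return The modified series.
#' @export
#' @examples
#' inject(rep(0, 10), injection("shift", onset_index = 6, magnitude = 5))
inject <- function(x, inj) {
  stopifnot(inherits(inj, "injection"))
  x <- as.numeric(x)
  n <- length(x)
  if (inj$kind == "spike") {
    hi <- inj$onset_index + inj$width - 1L
    if (inj$onset_index > n || hi > n) {
      abort("spike injection out of bounds.", class = "permclean_spec_error")
    }
    x[inj$onset_index:hi] <- x[inj$onset_index:hi] + inj$magnitude
  } else {
    if (inj$onset_index > n) {
      abort("shift injection out of bounds.", class = "permclean_spec_error")
    }
    x[inj$onset_index:n] <- x[inj$onset_index:n] + inj$magnitude
  }
  x
}

#' Specify a synthetic fermentation scenario
#'
#' Defaults describe a 40 h fed-batch: inoculation at 2 pF/cm, glycerol
#' batch growth at 0.12 1/h, substrate switch at 22 h followed by a smooth
#' 2 h adaptation dip (8% deep, not annotated as anomalous), methanol
#' fed-batch growth at 0.03 1/h, and additive Gaussian sensor noise of
#' 1 pF/cm — the probe's stated accuracy. Growth rates outside the
#' plausible 0.02–0.15 1/h band for methylotrophic yeast raise a warning.
#'
#' @param duration_h Total duration in hours.
#' @param sample_period_s Sampling period in seconds (default 60).
#' @param baseline Permittivity at inoculation (pF/cm).
#' @param mu_batch,mu_fedbatch Specific growth rates (1/h) before/after
#'   the substrate switch.
#' @param switch_time_h Time of the glycerol-to-methanol switch (h); set
#'   beyond `duration_h` for a single-phase run.
#' @param dip_depth_frac Fractional depth of the adaptation dip (0
#'   disables it).
#' @param dip_duration_h Duration of the dip (h).
#' @param plateau Stationary-phase cap on the clean signal (pF/cm).
#' @param noise_sigma Additive Gaussian noise standard deviation (pF/cm).
#' @param noise_prop_frac Optional signal-proportional noise component:
#'   standard deviation as a fraction of the clean value (default 0).
#' @param anomalies A list of [injection()]s.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec(duration_h = 10, seed = 42)
scenario_spec <- function(duration_h = 40,
                          sample_period_s = 60,
                          baseline = 2,
                          mu_batch = 0.12,
                          mu_fedbatch = 0.03,
                          switch_time_h = 22,
                          dip_depth_frac = 0.08,
                          dip_duration_h = 2,
                          plateau = 60,
                          noise_sigma = 1,
                          noise_prop_frac = 0,
                          anomalies = list(),
                          seed = 1L) {
  .assert_number(duration_h, "duration_h", 0, strict = TRUE)
  .assert_number(sample_period_s, "sample_period_s", 0, strict = TRUE)
  .assert_number(baseline, "baseline", 0, strict = TRUE)
  .assert_number(mu_batch, "mu_batch", 0, strict = TRUE)
  .assert_number(mu_fedbatch, "mu_fedbatch", 0, strict = TRUE)
  .assert_number(switch_time_h, "switch_time_h", 0, strict = TRUE)
  .assert_number(dip_depth_frac, "dip_depth_frac", 0)
  if (dip_depth_frac >= 1) {
    abort("`dip_depth_frac` must be below 1.", class = "permclean_spec_error")
  }
  .assert_number(dip_duration_h, "dip_duration_h", 0, strict = TRUE)
  .assert_number(plateau, "plateau", 0, strict = TRUE)
  .assert_number(noise_sigma, "noise_sigma", 0)
  .assert_number(noise_prop_frac, "noise_prop_frac", 0)
  for (mu in c(mu_batch, mu_fedbatch)) {
    if (mu < 0.02 - 1e-12 || mu > 0.15 + 1e-12) {
      warn(sprintf(
        "growth rate %.3g 1/h lies outside the plausible 0.02-0.15 1/h band.",
        mu))
    }
  }
  stopifnot(is.list(anomalies))
  anomalies <- lapply(anomalies, function(a) {
    if (!inherits(a, "injection")) {
      abort("`anomalies` must be a list of injection() objects.",
            class = "permclean_spec_error")
    }
    a
  })
  seed <- .assert_count(seed, "seed", 0L)
  structure(
    list(duration_h = duration_h, sample_period_s = sample_period_s,
         baseline = baseline, mu_batch = mu_batch,
         mu_fedbatch = mu_fedbatch, switch_time_h = switch_time_h,
         dip_depth_frac = dip_depth_frac, dip_duration_h = dip_duration_h,
         plateau = plateau, noise_sigma = noise_sigma,
         noise_prop_frac = noise_prop_frac, anomalies = anomalies,
         seed = seed),
    class = "scenario_spec"
  )
}

# Span of samples an injection marks as anomalous. A shift is annotated
# over a 15-sample transition window (one DRA context length): that is the
# span over which the signal is anomalous relative to its local context.
.injection_interval <- function(inj, n, shift_annot_len = 15L) {
  if (inj$kind == "spike") {
    c(inj$onset_index, min(n, inj$onset_index + inj$width - 1L))
  } else {
    c(inj$onset_index, min(n, inj$onset_index + shift_annot_len - 1L))
  }
}

#' Generate a synthetic permittivity trace with ground truth
#'
#' Builds the clean trace from the scenario, adds seeded Gaussian noise
#' and the injected anomalies, and returns per-injection annotation
#' intervals. Identical seeds give bit-identical output. Overlapping
#' injections are a specification error.
#'
#' @param spec A [scenario_spec()].
#'
#' @return An object of class `perm_scenario` with elements
#'   * `signal`: tibble `time_min`, `clean_pF_cm`, `permittivity_pF_cm`;
#'   * `annotations`: tibble `start`, `end` (sample indices), `start_min`,
#'     `end_min`, `label`;
#'   * `spec`: the input specification.
#' @export
#' @examples
#' sc <- generate_scenario(scenario_spec(duration_h = 6, seed = 7))
#' sc$signal
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  period_min <- spec$sample_period_s / 60
  n <- floor(spec$duration_h * 60 / period_min) + 1L
  time_min <- (seq_len(n) - 1L) * period_min
  t_h <- time_min / 60

  growth <- spec$baseline *
    exp(spec$mu_batch * pmin(t_h, spec$switch_time_h)) *
    exp(spec$mu_fedbatch * pmax(t_h - spec$switch_time_h, 0))
  clean <- pmin(growth, spec$plateau)

  if (spec$dip_depth_frac > 0 && spec$switch_time_h < spec$duration_h) {
    u <- (t_h - spec$switch_time_h) / spec$dip_duration_h
    in_dip <- u >= 0 & u <= 1
    trough <- 1 - spec$dip_depth_frac * (1 - cos(2 * pi * u[in_dip])) / 2
    clean[in_dip] <- clean[in_dip] * trough
  }

  # overlapping injections are ambiguous ground truth
  iv <- lapply(spec$anomalies, .injection_interval, n = n)
  if (length(iv) > 1L) {
    ord <- order(vapply(iv, `[`, numeric(1), 1L))
    iv_s <- iv[ord]
    for (i in seq_len(length(iv_s) - 1L)) {
      if (iv_s[[i + 1L]][1L] <= iv_s[[i]][2L]) {
        abort("overlapping injections.", class = "permclean_spec_error")
      }
    }
  }

  set.seed(spec$seed)
  noise <- rnorm(n, 0, spec$noise_sigma)
  if (spec$noise_prop_frac > 0) {
    noise <- noise + rnorm(n, 0, 1) * spec$noise_prop_frac * clean
  }
  noisy <- clean + noise
  for (a in spec$anomalies) noisy <- inject(noisy, a)

  annotations <- if (length(spec$anomalies)) {
    tibble(
      start = vapply(iv, function(v) as.integer(v[1L]), integer(1)),
      end = vapply(iv, function(v) as.integer(v[2L]), integer(1)),
      label = vapply(spec$anomalies, function(a) a$kind, character(1))
    )
  } else {
    tibble(start = integer(0), end = integer(0), label = character(0))
  }
  annotations$start_min <- time_min[annotations$start]
  annotations$end_min <- time_min[annotations$end]
  annotations <- annotations[, c("start", "end", "start_min", "end_min",
                                 "label")]

  structure(
    list(
      signal = tibble(time_min = time_min, clean_pF_cm = clean,
                      permittivity_pF_cm = noisy),
      annotations = annotations,
      spec = spec
    ),
    class = "perm_scenario"
  )
}

#' @export
print.perm_scenario <- function(x, ...) {
  cat(sprintf(
    "<perm_scenario> %d samples (%.1f h at %g s), %d injected anomal%s\n",
    nrow(x$signal), x$spec$duration_h, x$spec$sample_period_s,
    nrow(x$annotations), if (nrow(x$annotations) == 1L) "y" else "ies"))
  invisible(x)
}
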