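# Shared fixtures, built in code.

# Stationary-phase trace: the plateau cap holds the clean signal flat at
# `level`, isolating the correction machinery from growth-trend effects.
flat_scenario <- function(seed, n_min = 200, level = 10, noise_sigma = 0.2,
                          anomalies = list()) {
  generate_scenario(scenario_spec(
    duration_h = (n_min - 1) / 60, baseline = level, plateau = level,
    switch_time_h = n_min, noise_sigma = noise_sigma,
    anomalies = anomalies, seed = seed
  ))
}

# Pass-through smoother: exposes the raw samples to the DRA/detector so
# step responses are sharp. Used when testing detection and correction in
# isolation from the noise filter.
passthrough_config <- function(...) {
  pipeline_config(smoother = smoother_spec("moving_mean", w = 1), ...)
}

# Causal moving mean, computed independently of smooth_causal.
naive_causal_mean <- function(x, w) {
  vapply(seq_along(x), function(i) mean(x[max(1L, i - w + 1L):i]), numeric(1))
}
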