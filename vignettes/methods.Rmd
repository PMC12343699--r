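---
title: "Streaming cleanup of permittivity biomass signals: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming cleanup of permittivity biomass signals: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permclean)
```

## The problem and the model

An in-line permittivity probe reports a pF/cm value once per minute that
is proportional to viable cell density. Two kinds of sensor artifacts
corrupt it: transient spikes (an up-flank followed, within minutes, by a
down-flank of similar magnitude) and persistent baseline shifts. The
signal itself is non-stationary — its level grows roughly exponentially
with the culture and its noise amplitude changes over a run — so neither
a global outlier rule nor a fixed band on the raw values can separate
artifact from biology. The cleanup must also be *causal*: at minute *t*
only samples up to *t* exist.

`permclean` decomposes the problem into three streaming stages.

**Noise filtering.** A right-aligned window of the last `w` samples is
aggregated into one smoothed value per step. The default is a
Gaussian-weighted mean (`w = 70`, kernel standard deviation `w/5 = 14`
samples) centered on the newest sample; moving mean/median, a causal
Savitzky–Golay fit (degree 2), and causal local linear/quadratic
regression with tricube weights are available alternatives. Any such
filter trades noise suppression against latency; the nominal group delay
of a `w`-sample window is `(w - 1) / 2` samples, though the asymmetric
Gaussian kernel concentrates weight near the newest sample, so its
measured delay is far smaller (single-digit minutes at `w = 70`).

**Context removal.** The double rolling aggregate (DRA) transform
subtracts the mean of a context window (`w2 = 15`) from the mean of a
recent window (`w1 = 1`), both ending at the current sample. The result,
`perm_d`, is invariant to the local signal level — growth cancels out up
to its local slope — and responds to a jump of height *h* with an
excursion approaching `h * (w2 - 1) / w2`. A linear trend of slope *s*
per sample leaks through as a steady `s * (w2 - 1) / 2`, which is why
gradual process features (including the substrate-switch dip) stay below
threshold while sudden artifacts do not: gradualness, not magnitude,
governs detection.

**Detection, validation, removal.** `perm_d` is compared against a
threshold. The default is static, 1.06 pF/cm, applied two-sided: a
spike's down-flank is as informative as its up-flank, and sudden drops
must be caught as well. Three dynamic variants build a band
`location ± factor × scale` from the `w3` *previous* transformed values:
3-sigma (mean, sample standard deviation, factor 3), the Hampel
identifier (median, `b × MAD` with `b = 1.4826`, factor 3), and the IQR
rule (median, interquartile range, factor 2 ≈ ±2.7 σ under normality).
Flagged samples are replaced in the corrected output by the mean of the
previous 15 corrected values. When flagging stops, a 15-sample
validation window opens; new flags inside it merge into the same anomaly
group and restart the countdown, so every registered group is followed
by a full window of valid data. On completion the correction factor
`Fc = mean(15 validation-window levels) − mean(15 pre-anomaly corrected
values)` is added to the cumulative correction, which is subtracted from
every subsequent smoothed value. A spike's levels recover, so its Fc is
near zero; a shift's Fc equals its height and the corrected trace
continues the pre-anomaly baseline.

## Which signal feeds which buffer

The stage wiring is the one genuinely open design decision, and the
package resolves it by tracking three parallel histories:

* the **smoother** consumes the raw stream — the filter's job is to
  represent what the sensor reports, artifacts included;
* the **DRA context buffer** tracks the *level signal*
  `s(t) = smoothed(t) − fc_total`, including during flagged samples.
  This is load-bearing: if the context were frozen at the pre-anomaly
  baseline (e.g. fed the replacement values), a persistent shift would
  keep `perm_d ≈ h` forever — the anomaly could never close, validation
  could never start, and no shift could ever be compensated. Letting the
  context absorb the new level makes a shift's excursion decay by
  `h / w2` per sample, so flagging releases after roughly
  `w2 (1 − threshold/h)` samples and the validation window then measures
  the settled new level;
* the **output and replacement windows** consume corrected values, so
  the replacement mean holds the pre-anomaly baseline during an
  excursion and a downstream controller never sees it. For the dynamic
  thresholds the band-source window likewise receives, during flagged
  samples, the transform of the *replaced* value, so an anomaly cannot
  inflate the band that judges it (a volatility increase therefore
  raises the band only after the fact — an accepted property of
  backward-looking bands).

After each Fc fold the level buffer is rebased by the same amount;
otherwise the next sample's context difference would spuriously re-fire
by exactly `Fc`.

Fc is applied forward in time: a streaming consumer cannot revise the
past. For offline use `retro_correct()` rewrites history onto the final
baseline instead, adding to each sample the correction accumulated after
it.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| smoother `w` | 70 | samples | noise suppression vs latency |
| `gaussian_sigma` | `w/5` | samples | kernel width of the Gaussian filter |
| DRA `w1`, `w2` | 1, 15 | samples | recent vs context window; response to a jump ≈ `h(w2-1)/w2` |
| `static_value` | 1.06 | pF/cm | static decision threshold |
| `threshold_factor` | 3 (3-sigma, Hampel), 2 (IQR) | — | band half-width in scale units |
| `b_constant` | 1.4826 | — | MAD-to-sigma consistency under normality |
| `w3` | user-set | samples | rolling band window (≥ 120 advisable for 3-sigma: a window of `w` caps the attainable z-score at `(w-1)/sqrt(w)`, which only exceeds 3 beyond `w = 10`) |
| `validation_len` | 15 | samples | post-anomaly validation/merge window |
| `replacement_n` | 15 | samples | replacement and pre/post level means |

Defaults reproduce the reference operating point of the algorithm
(Gaussian `w = 70`; DRA 1/15 overlapping; static 1.06 pF/cm; both
15-sample windows at 1-minute sampling).

## Numerical choices and degenerate inputs

* Sample standard deviation uses the `n − 1` denominator; quantiles use
  linear interpolation between order statistics (type 7). Both matter on
  small `w3` windows and are therefore fixed and documented.
* Collapsed bands (zero scale, e.g. a constant window) flag only
  strictly nonzero deviations; `min_scale` lets users impose a floor.
  All decisions use strict inequalities, so a constant signal never
  flags under any rule.
* Warm-up: detection is suppressed until the longest configured window
  has filled, and the DRA emits the neutral value 0 while its context
  window is short. Cultivations start anomaly-free at near-zero biomass,
  so nothing is lost.
* Delay estimation mean-removes both series and evaluates the Pearson
  correlation over the overlapping support at each lag, breaking ties
  toward the smallest magnitude lag.
* Non-finite samples are sensor dropouts: flagged, replaced by the held
  baseline, and marked distinctly in the anomaly matrix. Time-grid gaps
  are an error unless `gap_fill` opts into the same dropout handling.
* Batch and streaming paths share the same arithmetic (identical window
  means), so replaying a series sample-by-sample reproduces the batch
  transform bit for bit.
* A run ending mid-anomaly closes the group at the last index with
  `Fc = 0` (no post samples exist to estimate a level); ending
  mid-validation finalizes Fc on the truncated window; both are flagged
  in the log and the matrix.

## The synthetic generator

`generate_scenario()` emulates the qualitative shape of a fed-batch
permittivity record: piecewise exponential growth (defaults 0.12 1/h
batch, 0.03 1/h fed-batch, inside the plausible 0.02–0.15 1/h band for
methylotrophic yeast on methanol), a smooth multiplicative cosine trough
at the substrate switch (default 8 % deep over 2 h — deliberately *not*
annotated, since the adaptation dip is biology, not artifact), an
optional stationary plateau, additive Gaussian noise, and injected
spike/shift anomalies whose samples form the ground-truth annotations. A
shift is annotated over a 15-sample transition window (one DRA context
length): that is the span over which the signal is anomalous relative to
its context, and it makes "detection overlaps the injection" meaningful
under a delayed, smoothed detector.

The default noise level is 1 pF/cm, the stated accuracy of the
measuring probe class; calibrating the noise to reproduce a particular
campaign's raw NRMSE instead would require a noise floor incompatible
with the default 1.06 pF/cm threshold, so the probe-accuracy calibration
was chosen. What the generator does **not** emulate: conductivity-driven
changes in noise amplitude over a run, autocorrelated sensor noise,
mechanistic substrate/oxygen dynamics, or the empirical magnitude
distribution of real artifacts (spike/shift sizes are scenario
parameters, defaulting to the 2–10 pF/cm range). Passing tests on
synthetic traces therefore demonstrate the machinery's correctness and
calibration behavior, not field performance on any particular reactor.

## Problem sizes in the shipped experiments

The recovery experiments run on stationary-phase traces (plateau-capped,
so the clean level is flat) of 200 one-minute samples with noise
σ = 0.2 pF/cm, a pass-through smoother, and the default DRA/threshold:
100 seeded replicates per shift height (2, 5, 10 pF/cm) and 100 spike
replicates (height 8 pF/cm, widths 3–10). The flat trace and bypassed
smoother isolate the correction machinery: the Fc tolerance
`4σ/sqrt(15)` is the sampling error of two 15-sample means and leaves no
room for growth-trend bias (see limitations). Streaming/batch
equivalence uses 50 random-walk series up to length 500; delay recovery
uses every integer lag in ±20 on 500-sample random walks; band
equivariance uses 1,000 random windows.

## Known limitations

* **Trend bias in Fc.** The pre- and post-anomaly windows are separated
  by the anomaly's duration plus the validation window; any real growth
  in between is absorbed into Fc. At 0.05 1/h on a 30 pF/cm signal this
  is ~0.5 pF/cm over a typical episode — visible in the worked example's
  recovered 10.5 for a true 10. A growth-aware Fc (detrending the two
  windows) would remove this but is deliberately out of scope.
* **Smoothing smears spikes.** Under the heavy default filter a spike's
  energy leaks into the validation window, leaving a small spurious Fc;
  with the pass-through smoother the residual vanishes. Detection of
  short spikes also weakens as `w` grows: a step must reach roughly
  three times the threshold to fire through the default filter.
* **Detection lags onset** by the smoothing delay plus the DRA response
  time; per-sample recall is structurally below 1 at the flanks.
* **Backward-looking dynamic bands** respond to volatility changes with
  a `w3`-sample delay by construction.
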