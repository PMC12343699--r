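# Streaming anomaly logging, value replacement, validation/merging and
# shift compensation via the cumulative correction factor Fc.
#
# Per sample the detector (i) smooths causally, (ii) subtracts the
# cumulative correction fc_total to get the level-tracked signal
# s = smoothed - fc_total, (iii) computes the DRA transform of s against
# its own recent history, and (iv) threshold-decides. Flagged samples are
# replaced in the *output* by the mean of the last `replacement_n`
# corrected values (a held baseline, so a controller consuming the
# corrected signal never sees the excursion). Once the anomaly passes, a
# validation period of `validation_len` samples estimates the new signal
# level; anomalies re-firing during validation are merged into the same
# group and restart the countdown, guaranteeing that a full validation
# window of valid data follows the last flank. When the countdown
# completes, Fc = (post-anomaly mean) - (pre-anomaly mean) is folded into
# fc_total so all subsequent samples are brought back onto the
# pre-anomaly baseline.
#
# The DRA context buffer deliberately tracks s(t), not the replaced
# output: a persistent shift must be absorbed by the context window for
# the anomaly to close and for the validation window to measure the new
# level. The replaced values feed the output, the replacement and
# pre-anomaly-mean windows, and (for dynamic thresholds) the band-source
# window, which therefore never ingests the anomaly's own transformed
# excursions.

#' Replacement value for an anomalous sample
#'
#' Mean of the most recent `n` corrected values; with a shorter history
#' (warm-up) all available values are used.
#'
#' @param history Numeric vector of corrected values, oldest first.
#' @param n Window length (default 15).
#'
#' @return A single value in pF/cm.
#' @export
#' @examples
#' replacement_value(1:15) # 8
replacement_value <- function(history, n = 15L) {
  n <- .assert_count(n, "n", 1L)
  if (length(history) == 0L) {
    abort("empty history: no values available for replacement.",
          class = "permclean_state_error")
  }
  mean(tail(as.numeric(history), n))
}

#' Correction factor from pre/post anomaly levels
#'
#' `Fc = post_mean - pre_mean`: the difference between the mean signal
#' level over the validation window after an anomaly and the mean level
#' immediately before it. Folded into the cumulative correction, it
#' compensates persistent shifts; for spikes the signal returns to its
#' previous level and Fc is near zero.
#'
#' @param pre_mean Mean level before the anomaly (pF/cm).
#' @param post_mean Mean level over the validation window (pF/cm).
#'
#' @return Fc in pF/cm.
#' @export
#' @examples
#' compute_fc(10, 12) # 2
compute_fc <- function(pre_mean, post_mean) {
  post_mean - pre_mean
}

#' Initialize streaming detector state
#'
#' @param config A [pipeline_config()].
#'
#' @return An object of class `detector_state`, to be threaded through
#'   [detector_step()] and closed with [detector_finish()].
#' @export
detector_init <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  structure(
    list(
      config = config,
      t = 0L,
      fc_total = 0,
      raw_buf = numeric(0),     # smoother input, raw scale
      level_buf = numeric(0),   # s = smoothed - fc_total
      out_buf = numeric(0),     # corrected output values
      pd_window = numeric(0),   # band-source transformed values (dynamic)
      in_anomaly = FALSE,
      open_start = NA_integer_,
      open_end = NA_integer_,
      open_dropout = FALSE,
      pre_mean = NA_real_,
      valid_count = 0L,
      post_vals = numeric(0),
      rows = list(),
      log = character(0)
    ),
    class = "detector_state"
  )
}

#' Advance the detector by one sample
#'
#' Processes a single raw permittivity value and returns the updated state
#' together with a one-sample record. Non-finite raw values are treated as
#' sensor dropouts: flagged as anomalous, replaced, and logged distinctly.
#'
#' @param state A `detector_state` from [detector_init()] or a previous
#'   step.
#' @param raw The raw permittivity value (pF/cm) for this sample.
#'
#' @return A list with elements `state` (updated) and `record` (a named
#'   list: `raw`, `smoothed`, `corrected`, `perm_d`, `anomaly_flag`,
#'   `fc_total`, `threshold_lower`, `threshold_upper`, `dropout`).
#' @export
detector_step <- function(state, raw) {
  stopifnot(inherits(state, "detector_state"))
  cfg <- state$config
  thr <- cfg$threshold
  t <- state$t + 1L
  fc <- state$fc_total
  dropout <- !is.finite(raw)

  if (dropout) {
    if (length(state$out_buf) == 0L) {
      abort("stream begins with a non-finite value: no history to hold.",
            class = "permclean_state_error")
    }
    smoothed <- NA_real_
    s_val <- tail(state$out_buf, 1L)  # hold the last corrected level
    raw_input <- s_val + fc
  } else {
    raw_input <- raw
    smoothed <- smooth_causal(c(state$raw_buf, raw), cfg$smoother)
    s_val <- smoothed - fc
  }

  pd <- dra_value(c(state$level_buf, s_val), cfg$dra)

  warm <- t <= cfg$warmup
  if (thr$kind == "static") {
    band_lower <- if (thr$two_sided) -thr$static_value else -Inf
    band_upper <- thr$static_value
    flag_stat <- !warm && static_decide(pd, thr)
  } else if (length(state$pd_window) == thr$w3) {
    bv <- .band_kernel(state$pd_window, thr)
    band_lower <- bv[2L]
    band_upper <- bv[3L]
    flag_stat <- !warm &&
      (if (thr$two_sided) pd < bv[2L] || pd > bv[3L] else pd > bv[3L])
  } else {
    band_lower <- NA_real_
    band_upper <- NA_real_
    flag_stat <- FALSE
  }
  flag <- dropout || flag_stat

  level_buf_old <- state$level_buf
  fc_delta <- 0

  if (flag) {
    if (state$in_anomaly) {
      state$open_end <- t
    } else if (state$valid_count > 0L) {
      # new flank within the validation period: merge into the open group
      state$in_anomaly <- TRUE
      state$open_end <- t
      state$valid_count <- 0L
      state$post_vals <- numeric(0)
    } else {
      state$in_anomaly <- TRUE
      state$open_start <- t
      state$open_end <- t
      state$open_dropout <- FALSE
      state$pre_mean <- if (length(state$out_buf)) {
        mean(tail(state$out_buf, cfg$replacement_n))
      } else {
        s_val
      }
    }
    if (dropout) state$open_dropout <- TRUE
    corrected <- if (length(state$out_buf)) {
      replacement_value(state$out_buf, cfg$replacement_n)
    } else {
      s_val
    }
    pd_src <- dra_value(c(level_buf_old, corrected), cfg$dra)
  } else {
    if (state$in_anomaly) {
      # anomaly just passed: start (or restart) validation
      state$in_anomaly <- FALSE
      state$valid_count <- cfg$validation_len
      state$post_vals <- numeric(0)
    }
    if (state$valid_count > 0L) {
      state$post_vals <- c(state$post_vals, s_val)
      corrected <- replacement_value(state$out_buf, cfg$replacement_n)
      state$valid_count <- state$valid_count - 1L
      if (state$valid_count == 0L) {
        fc_delta <- compute_fc(state$pre_mean, mean(state$post_vals))
        state$fc_total <- state$fc_total + fc_delta
        state$rows[[length(state$rows) + 1L]] <- list(
          start = state$open_start, end = state$open_end, fc = fc_delta,
          truncated = FALSE, dropout = state$open_dropout
        )
        state$log <- c(state$log, sprintf(
          "anomaly samples %d-%d closed, Fc = %.6g pF/cm%s",
          state$open_start, state$open_end, fc_delta,
          if (state$open_dropout) " (includes sensor dropout)" else ""
        ))
        state$open_start <- NA_integer_
        state$open_end <- NA_integer_
        state$open_dropout <- FALSE
        state$pre_mean <- NA_real_
        state$post_vals <- numeric(0)
      }
    } else {
      corrected <- s_val
    }
    pd_src <- pd
  }

  # Buffer maintenance. After an Fc fold the level history is rebased so
  # the context window stays continuous with the new fc_total.
  state$raw_buf <- tail(c(state$raw_buf, raw_input), cfg$smoother$w)
  lev <- tail(c(level_buf_old, s_val), .dra_need(cfg$dra))
  if (fc_delta != 0) lev <- lev - fc_delta
  state$level_buf <- lev
  state$out_buf <- tail(c(state$out_buf, corrected), cfg$replacement_n)
  if (thr$kind != "static") {
    state$pd_window <- tail(c(state$pd_window, pd_src), thr$w3)
  }
  state$t <- t

  list(
    state = state,
    record = list(raw = if (dropout) NA_real_ else raw, smoothed = smoothed,
                  corrected = corrected, perm_d = pd, anomaly_flag = flag,
                  fc_total = state$fc_total,
                  threshold_lower = band_lower, threshold_upper = band_upper,
                  dropout = dropout)
  )
}

#' Close a streaming run and collect the anomaly matrix
#'
#' Any anomaly still open at the end of the stream is closed at the final
#' index; a pending validation finalizes Fc with the post samples
#' available so far (fewer than the full window), which is flagged as
#' truncated in the matrix and noted in the log.
#'
#' @param state A `detector_state`.
#'
#' @return A list with `anomalies` (tibble: `start`, `end` sample indices,
#'   `fc`, `truncated`, `dropout`), `fc_total`, and `log` (character).
#' @export
detector_finish <- function(state) {
  stopifnot(inherits(state, "detector_state"))
  rows <- state$rows
  log <- state$log
  if (state$in_anomaly) {
    fc_delta <- 0  # no post-anomaly samples: the shift cannot be estimated
    rows[[length(rows) + 1L]] <- list(
      start = state$open_start, end = state$open_end, fc = fc_delta,
      truncated = TRUE, dropout = state$open_dropout
    )
    log <- c(log, sprintf(
      "run ended inside anomaly %d-%d: no validation samples, Fc set to 0",
      state$open_start, state$open_end))
  } else if (state$valid_count > 0L) {
    fc_delta <- compute_fc(state$pre_mean, mean(state$post_vals))
    state$fc_total <- state$fc_total + fc_delta
    rows[[length(rows) + 1L]] <- list(
      start = state$open_start, end = state$open_end, fc = fc_delta,
      truncated = TRUE, dropout = state$open_dropout
    )
    log <- c(log, sprintf(
      "run ended mid-validation: Fc = %.6g pF/cm from %d post samples (truncated window)",
      fc_delta, length(state$post_vals)))
  }
  anomalies <- if (length(rows)) {
    tibble(
      start = vapply(rows, function(r) as.integer(r$start), integer(1)),
      end = vapply(rows, function(r) as.integer(r$end), integer(1)),
      fc = vapply(rows, function(r) as.numeric(r$fc), numeric(1)),
      truncated = vapply(rows, function(r) r$truncated, logical(1)),
      dropout = vapply(rows, function(r) r$dropout, logical(1))
    )
  } else {
    tibble(start = integer(0), end = integer(0), fc = numeric(0),
           truncated = logical(0), dropout = logical(0))
  }
  list(anomalies = anomalies, fc_total = state$fc_total, log = log)
}
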