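# Double rolling aggregate (DRA) context-removal transform.
#
# Two windows move along the series in parallel; the transformed value is
# (aggregate of the recent w1 window) minus (aggregate of the w2 context
# window). Subtracting the context kills the local mean, so the transform
# is invariant to constant offsets and exposes sudden level changes: an
# upward jump gives a positive transformed value.

.dra_need <- function(spec) {
  if (spec$mode == "overlapping") max(spec$w1, spec$w2) else spec$w1 + spec$w2
}

#' One-step DRA transform
#'
#' Computes the DRA-transformed value for the newest sample of a buffer.
#' While the buffer is too short to fill both windows (warm-up), the
#' neutral value 0 is returned so that no spurious detections can arise
#' before the context window fills.
#'
#' @param buffer Numeric vector of recent values, ordered oldest to newest.
#' @param spec A [dra_spec()].
#'
#' @return A single transformed value (same units as the input).
#' @export
#' @examples
#' dra_value(c(rep(0, 14), 1), dra_spec(w1 = 1, w2 = 15)) # 14/15
dra_value <- function(buffer, spec) {
  stopifnot(inherits(spec, "dra_spec"))
  b <- as.numeric(buffer)
  n <- length(b)
  if (n < .dra_need(spec)) return(0)
  a1 <- mean(b[(n - spec$w1 + 1L):n])
  a2 <- if (spec$mode == "overlapping") {
    mean(b[(n - spec$w2 + 1L):n])
  } else {
    mean(b[(n - spec$w1 - spec$w2 + 1L):(n - spec$w1)])
  }
  a1 - a2
}

#' DRA transform of a full series
#'
#' Applies [dra_value()] over a sliding causal buffer, so the result at
#' index `i` depends only on samples up to `i`. The output has the same
#' length as the input; warm-up positions are 0. The per-index arithmetic
#' is identical to the streaming path, so replaying a series sample by
#' sample reproduces this output exactly.
#'
#' @param data A data frame with a `permittivity_pF_cm` column (a `perm_d`
#'   column is added), or a bare numeric vector (a numeric vector is
#'   returned).
#' @param spec A [dra_spec()].
#'
#' @return Same shape as the input (tibble with `perm_d`, or numeric).
#' @export
#' @examples
#' dra_series(c(rep(0, 20), rep(1, 20)), dra_spec(w1 = 1, w2 = 15))
dra_series <- function(data, spec) {
  stopifnot(inherits(spec, "dra_spec"))
  if (is.data.frame(data)) {
    x <- data$permittivity_pF_cm
    if (is.null(x)) {
      abort("`data` must have a `permittivity_pF_cm` column.",
            class = "permclean_input_error")
    }
  } else if (is.numeric(data)) {
    x <- as.numeric(data)
  } else {
    abort("`data` must be a data frame or a numeric vector.",
          class = "permclean_input_error")
  }
  n <- length(x)
  need <- .dra_need(spec)
  w1 <- spec$w1; w2 <- spec$w2
  out <- numeric(n)
  if (spec$mode == "overlapping") {
    for (i in seq_len(n)) {
      if (i >= need) {
        out[i] <- mean(x[(i - w1 + 1L):i]) - mean(x[(i - w2 + 1L):i])
      }
    }
  } else {
    for (i in seq_len(n)) {
      if (i >= need) {
        out[i] <- mean(x[(i - w1 + 1L):i]) -
          mean(x[(i - w1 - w2 + 1L):(i - w1)])
      }
    }
  }
  if (is.data.frame(data)) {
    res <- as_tibble(data)
    res$perm_d <- out
    res
  } else {
    out
  }
}
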