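test_that("replacement value is the mean of the recent corrected history", {
  expect_equal(replacement_value(rep(10, 40)), 10)
  expect_equal(replacement_value(1:15), 8)
  expect_equal(replacement_value(1:100, n = 15), mean(86:100))
  # warm-up fallback: shorter history is used in full
  expect_equal(replacement_value(rep(2, 5)), 2)
  expect_error(replacement_value(numeric(0)),
               class = "permclean_state_error")
})

test_that("the correction factor is the post/pre level difference", {
  expect_equal(compute_fc(10, 10), 0)
  expect_equal(compute_fc(10, 12), 2)
  expect_equal(compute_fc(3.5, 1.25), -2.25)
})

test_that("clean constant input never flags and passes through", {
  run <- run_pipeline(rep(12.5, 120), passthrough_config())
  expect_equal(nrow(tidy(run)), 0L)
  expect_false(any(run$data$anomaly_flag))
  expect_equal(run$data$corrected, run$data$smoothed)
  expect_equal(run$fc_total, 0)
})

test_that("a noiseless step is registered, compensated and removed", {
  x <- c(rep(10, 100), rep(15, 100))
  run <- run_pipeline(x, passthrough_config())
  m <- tidy(run)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 101L)
  expect_equal(run$fc_total, 5)
  expect_equal(sum(m$fc), run$fc_total)
  # after compensation the corrected trace is restored to the old baseline
  expect_equal(run$data$corrected, rep(10, 200), tolerance = 1e-9)
})

test_that("a noiseless symmetric spike merges into one group with near-zero Fc", {
  x <- rep(10, 200)
  x[81:83] <- x[81:83] + 5   # up 5 for 3 samples, back down
  run <- run_pipeline(x, passthrough_config())
  m <- tidy(run)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 81L)
  expect_equal(abs(run$fc_total), 0, tolerance = 1e-9)
  # held baseline: the excursion never reaches the corrected output
  expect_equal(max(abs(run$data$corrected - 10)), 0, tolerance = 1e-9)
})

test_that("flanks separated by a sub-threshold gap still merge during validation", {
  # width-10 spike of 2.5 pF/cm: the up-flank decision releases before the
  # down-flank fires, leaving a non-flagged gap that the validation period
  # must bridge into a single registered anomaly
  x <- rep(10, 200)
  x[80:89] <- x[80:89] + 2.5
  run <- run_pipeline(x, passthrough_config())
  flags <- which(run$data$anomaly_flag)
  expect_gt(max(diff(flags)), 1L)          # a genuine gap existed
  expect_equal(nrow(tidy(run)), 1L)        # yet one anomaly row
  expect_equal(abs(run$fc_total), 0, tolerance = 1e-9)
})

test_that("registered anomaly groups are separated by full validation windows", {
  set.seed(21)
  for (seed in 1:5) {
    sc <- flat_scenario(seed, n_min = 400, anomalies = list(
      injection("shift", onset_index = 80, magnitude = 4),
      injection("spike", onset_index = 200, magnitude = 6, width = 4),
      injection("shift", onset_index = 320, magnitude = -3)
    ))
    run <- run_pipeline(sc$signal, passthrough_config())
    m <- tidy(run)
    if (nrow(m) >= 2L) {
      gaps <- m$start[-1L] - m$end[-nrow(m)] - 1L
      expect_true(all(gaps >= run$config$validation_len))
    }
    # conservation: the cumulative correction is the sum of per-group Fc
    expect_equal(run$fc_total, sum(m$fc), tolerance = 1e-12)
  }
})

test_that("a run ending mid-anomaly closes at the final sample", {
  x <- c(rep(10, 100), rep(20, 10))  # stream stops while still shifted
  run <- run_pipeline(x, passthrough_config())
  m <- tidy(run)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end[1], 110L)
  expect_true(m$truncated[1])
  expect_match(paste(run$log, collapse = "\n"), "ended inside anomaly")
})

test_that("a run ending mid-validation finalizes Fc on the truncated window", {
  x <- c(rep(10, 100), rep(15, 20))  # flanks flag ~12 samples; 8 post samples
  run <- run_pipeline(x, passthrough_config())
  m <- tidy(run)
  expect_equal(nrow(m), 1L)
  expect_true(m$truncated[1])
  expect_equal(run$fc_total, 5, tolerance = 1e-9)
  expect_match(paste(run$log, collapse = "\n"), "mid-validation")
})

test_that("non-finite samples are treated as logged sensor dropouts", {
  x <- rep(10, 120)
  x[60:62] <- NA
  run <- run_pipeline(x, passthrough_config())
  expect_equal(sum(run$data$dropout), 3L)
  expect_true(all(run$data$anomaly_flag[60:62]))
  expect_equal(run$data$corrected[60:62], rep(10, 3))
  m <- tidy(run)
  expect_equal(nrow(m), 1L)
  expect_true(m$dropout[1])
  expect_equal(run$fc_total, 0, tolerance = 1e-9)

  expect_error(run_pipeline(c(NA, rep(10, 20)), passthrough_config()),
               class = "permclean_state_error")
})

test_that("no detection occurs during warm-up", {
  # an immediate step lands inside the warm-up window and must not flag,
  # while the same step later in the stream does
  cfg <- passthrough_config()
  # the step sits so early that by the end of warm-up the context window
  # has already absorbed the new level: nothing left to flag
  early <- c(rep(10, 2), rep(15, 43))
  expect_equal(nrow(tidy(run_pipeline(early, cfg))), 0L)
  late <- c(rep(10, 40), rep(15, 40))
  expect_equal(nrow(tidy(run_pipeline(late, cfg))), 1L)
})

test_that("replaying the same input yields identical results", {
  sc <- flat_scenario(31, anomalies = list(
    injection("shift", onset_index = 100, magnitude = 5)))
  r1 <- run_pipeline(sc$signal, passthrough_config())
  r2 <- run_pipeline(sc$signal, passthrough_config())
  expect_identical(r1$data, r2$data)
  expect_identical(r1$anomalies, r2$anomalies)
})

test_that("dynamic thresholds run the same machinery without band poisoning", {
  sc <- flat_scenario(41, n_min = 300, anomalies = list(
    injection("shift", onset_index = 150, magnitude = 5)))
  cfg <- passthrough_config(
    threshold = threshold_spec("hampel", w3 = 30, min_scale = 0.05))
  run <- run_pipeline(sc$signal, cfg)
  m <- tidy(run)
  expect_gte(nrow(m), 1L)
  expect_true(any(m$start <= 152 & m$end >= 150))
  expect_equal(run$fc_total, 5, tolerance = 0.3)
  # band edges are recorded once the window fills
  expect_true(anyNA(run$data$threshold_upper[1:30]))
  expect_false(anyNA(run$data$threshold_upper[100:140]))
})

test_that("the streaming step API matches the batch wrapper", {
  sc <- flat_scenario(51, n_min = 150, anomalies = list(
    injection("spike", onset_index = 70, magnitude = 6, width = 4)))
  cfg <- passthrough_config()
  state <- detector_init(cfg)
  corrected <- numeric(150)
  for (i in 1:150) {
    res <- detector_step(state, sc$signal$permittivity_pF_cm[i])
    state <- res$state
    corrected[i] <- res$record$corrected
  }
  fin <- detector_finish(state)
  run <- run_pipeline(sc$signal, cfg)
  expect_identical(corrected, run$data$corrected)
  expect_identical(fin$anomalies$start, run$anomalies$start)
  expect_identical(fin$fc_total, run$fc_total)
})
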