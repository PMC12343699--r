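test_that("series and annotation CSVs round-trip", {
  sc <- flat_scenario(81, n_min = 60, anomalies = list(
    injection("spike", onset_index = 30, magnitude = 8, width = 3)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_permittivity_csv(sc$signal, f, digits = 10)
  back <- read_permittivity_csv(f)
  expect_equal(names(back), c("time_min", "permittivity_pF_cm"))
  expect_equal(back$permittivity_pF_cm, sc$signal$permittivity_pF_cm,
               tolerance = 1e-8)

  fa <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(sc$annotations, fa)
  ann <- read_annotations_csv(fa)
  expect_equal(ann$start_min, sc$annotations$start_min)
  expect_equal(ann$label, "spike")

  expect_error(read_permittivity_csv(fa), class = "permclean_input_error")
})

test_that("pipeline configurations round-trip losslessly through YAML", {
  cfg <- pipeline_config(
    smoother = smoother_spec("savitzky_golay", w = 21, poly_degree = 2),
    dra = dra_spec(w1 = 2, w2 = 10, mode = "adjacent"),
    threshold = threshold_spec("hampel", w3 = 24, threshold_factor = 2.5,
                               min_scale = 0.01),
    validation_len = 10, replacement_n = 12, sample_period_s = 30,
    gap_fill = TRUE)
  f <- withr::local_tempfile(fileext = ".yml")
  write_pipeline_config(cfg, f)
  back <- read_pipeline_config(f)
  expect_equal(unclass(back$smoother), unclass(cfg$smoother))
  expect_equal(unclass(back$dra), unclass(cfg$dra))
  expect_equal(unclass(back$threshold), unclass(cfg$threshold))
  expect_equal(back$validation_len, cfg$validation_len)
  expect_equal(back$replacement_n, cfg$replacement_n)
  expect_equal(back$sample_period_s, cfg$sample_period_s)
  expect_equal(back$warmup, cfg$warmup)
  expect_equal(back$gap_fill, cfg$gap_fill)

  # defaults reproduce the reference operating point
  def <- pipeline_config()
  expect_equal(def$smoother$method, "gaussian")
  expect_equal(def$smoother$w, 70L)
  expect_equal(def$dra$w1, 1L)
  expect_equal(def$dra$w2, 15L)
  expect_equal(def$threshold$static_value, 1.06)
  expect_equal(def$validation_len, 15L)
  expect_equal(def$replacement_n, 15L)
})

test_that("run outputs are written with the documented headers, byte-identically", {
  sc <- flat_scenario(82, n_min = 120, anomalies = list(
    injection("shift", onset_index = 60, magnitude = 5)))
  run <- run_pipeline(sc$signal, passthrough_config())
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  fa <- withr::local_tempfile(fileext = ".csv")
  write_run_outputs(run, f1, anomalies_path = fa)
  write_run_outputs(run_pipeline(sc$signal, passthrough_config()), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(readLines(f1)[1],
               paste("time_min,raw,smoothed,corrected,perm_d",
                     "threshold_lower,threshold_upper,anomaly_flag,fc_total",
                     sep = ","))
  expect_equal(readLines(fa)[1], "start_min,end_min")
})

test_that("time-grid gaps are an error unless gap-fill is enabled", {
  sc <- flat_scenario(83, n_min = 60)
  holey <- sc$signal[-c(30, 31), ]
  expect_error(run_pipeline(holey, passthrough_config()),
               class = "permclean_input_error")
  run <- run_pipeline(holey, passthrough_config(gap_fill = TRUE))
  expect_equal(nrow(run$data), 60L)
  expect_equal(sum(run$data$dropout), 2L)
})

test_that("runs accept bare numeric vectors", {
  run <- run_pipeline(rep(3, 50), passthrough_config())
  expect_equal(run$data$time_min, 0:49)
})

test_that("broom-style accessors expose the run object", {
  sc <- flat_scenario(84, n_min = 150, anomalies = list(
    injection("shift", onset_index = 70, magnitude = 5)))
  run <- run_pipeline(sc$signal, passthrough_config())
  g <- glance(run)
  expect_equal(g$n, 150L)
  expect_equal(g$n_anomalies, nrow(tidy(run)))
  expect_equal(g$fc_total, run$fc_total)
  expect_s3_class(augment(run), "tbl_df")
  expect_equal(nrow(augment(run)), 150L)
  expect_output(print(run), "anomaly_run")
})

test_that("autoplot methods return ggplot objects", {
  sc <- flat_scenario(85, n_min = 100, anomalies = list(
    injection("spike", onset_index = 50, magnitude = 8, width = 3)))
  run <- run_pipeline(sc$signal, passthrough_config())
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(run), "patchwork")
})

test_that("retroactive alignment rewrites history onto the final baseline", {
  x <- c(rep(10, 100), rep(15, 100))
  run <- run_pipeline(x, passthrough_config())
  retro <- retro_correct(run)
  expect_equal(retro$corrected_retro,
               run$data$corrected + (run$fc_total - run$data$fc_total))
  # streaming correction keeps the old baseline; retro sits on the new one
  expect_equal(tail(retro$corrected_retro, 1), tail(run$data$corrected, 1))
  expect_equal(retro$corrected_retro[1] - run$data$corrected[1],
               run$fc_total)
})

test_that("the command-line front end drives the package end to end", {
  script <- system.file("scripts", "permclean", package = "permclean")
  skip_if(script == "", "CLI script not installed")
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  dir <- withr::local_tempdir()
  series <- file.path(dir, "series.csv")
  ann <- file.path(dir, "ann.csv")
  out <- file.path(dir, "out.csv")
  anom <- file.path(dir, "anom.csv")
  rscript <- file.path(R.home("bin"), "Rscript")
  r1 <- system2(rscript, c(script, "generate", "--out", series,
                           "--annotations", ann, "--seed", "4",
                           "--duration-h", "4", "--shift", "2,10"),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(series) && file.exists(ann))
  r2 <- system2(rscript, c(script, "run", "--in", series, "--out", out,
                           "--anomalies", anom),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.exists(anom))
  d <- readr::read_csv(out, show_col_types = FALSE)
  expect_true(all(c("perm_d", "anomaly_flag", "fc_total") %in% names(d)))
  r3 <- system2(rscript, c(script, "evaluate", "--run", out,
                           "--annotations", ann),
                stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("f1", r3)) || any(grepl("precision", r3)))
})
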