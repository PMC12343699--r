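test_that("static threshold flags magnitude exceedances", {
  spec <- threshold_spec("static", static_value = 1.06)
  expect_true(static_decide(1.07, spec))
  expect_false(static_decide(0, spec))
  expect_false(static_decide(1.06, spec)) # strict inequality
  # spikes are followed by a drop of similar magnitude: both signs count
  expect_true(static_decide(-1.20, spec))
  one_sided <- threshold_spec("static", static_value = 1.06,
                              two_sided = FALSE)
  expect_false(static_decide(-1.20, one_sided))
  # constant signal transforms to zero, hence never flags
  expect_false(any(static_decide(rep(0, 100), spec)))
})

test_that("3-sigma band uses mean and sample (n-1) standard deviation", {
  b <- band_three_sigma(1:10, factor = 3)
  expect_equal(b$center, 5.5)
  expect_equal(b$upper, 5.5 + 3 * sqrt(82.5 / 9), tolerance = 1e-12)
  expect_equal(b$lower, -3.583, tolerance = 1e-4)
  expect_equal(b$upper, 14.583, tolerance = 1e-4)

  collapsed <- band_three_sigma(rep(5, 12))
  expect_equal(c(collapsed$center, collapsed$lower, collapsed$upper),
               c(5, 5, 5))
})

test_that("Hampel band matches the hand-computed MAD example", {
  b <- band_hampel(c(1, 2, 3, 4, 100), factor = 3, b = 1.4826)
  expect_equal(b$center, 3)
  expect_equal(b$lower, -1.4478, tolerance = 1e-4)
  expect_equal(b$upper, 7.4478, tolerance = 1e-4)
  expect_gt(100, b$upper) # the outlier lies outside its own window's band

  expect_equal(band_hampel(rep(2.2, 9))$upper, 2.2)
  # symmetric window: center is exactly 0
  expect_equal(band_hampel(c(-3, -1, 0, 1, 3))$center, 0)
})

test_that("IQR band uses linear-interpolation quantiles", {
  b <- band_iqr(1:5, factor = 2)
  expect_equal(c(b$center, b$lower, b$upper), c(3, -1, 7))
  expect_equal(band_iqr(rep(1.5, 8))$lower, 1.5)
})

test_that("IQR/1.349 is a consistent estimate of sigma for normal data", {
  set.seed(123)
  x <- rnorm(1e5)
  qs <- quantile(x, c(0.25, 0.75), names = FALSE)
  sigma_hat <- (qs[2] - qs[1]) / (qnorm(0.75) - qnorm(0.25))
  expect_lt(abs(sigma_hat - sd(x)) / sd(x), 0.05)
})

test_that("dynamic decisions use the band strictly and exclude the current sample", {
  spec3 <- threshold_spec("three_sigma", w3 = 120)
  # collapsed band on a constant window: strict rule flags nonzero deviation
  expect_true(dynamic_decide(0.5, rep(0, 120), spec3))
  expect_false(dynamic_decide(0, rep(0, 120), spec3))

  set.seed(11)
  win150 <- rnorm(150)
  expect_true(dynamic_decide(10, win150,
                             threshold_spec("three_sigma", w3 = 150)))
  expect_true(dynamic_decide(10, win150,
                             threshold_spec("hampel", w3 = 150)))
  expect_true(dynamic_decide(10, win150, threshold_spec("iqr", w3 = 150)))
  # a value inside the band never flags
  expect_false(dynamic_decide(mean(win150), win150,
                              threshold_spec("three_sigma", w3 = 150)))
  # the window must hold exactly w3 past values
  expect_error(dynamic_decide(1, rnorm(10),
                              threshold_spec("hampel", w3 = 20)),
               class = "permclean_parameter_error")
})

test_that("maximum attainable threshold factor bounds small-window detection", {
  expect_equal(max_threshold_factor(4), 1.5)
  expect_lt(max_threshold_factor(10), 3)   # 9/sqrt(10) = 2.846
  expect_gt(max_threshold_factor(11), 3)
  w <- 2:200
  expect_true(all(diff(max_threshold_factor(w)) > 0))
  expect_error(max_threshold_factor(1), class = "permclean_parameter_error")

  # consequence: with factor 3 and w <= 10, no in-window point can flag
  set.seed(12)
  for (i in 1:30) {
    win <- rnorm(sample(2:10, 1), sd = runif(1, 0.1, 10))
    b <- band_three_sigma(win, factor = 3)
    expect_true(all(win >= b$lower & win <= b$upper))
  }
})

test_that("all threshold bands are affine-equivariant", {
  set.seed(13)
  for (i in 1:200) {
    win <- rnorm(sample(4:40, 1))
    a <- runif(1, 0.1, 5)
    c0 <- runif(1, -20, 20)
    for (f in list(function(x) band_three_sigma(x, 3),
                   function(x) band_hampel(x, 3),
                   function(x) band_iqr(x, 2))) {
      b0 <- f(win)
      b1 <- f(a * win + c0)
      expect_equal(b1$center, a * b0$center + c0, tolerance = 1e-9)
      expect_equal(b1$lower, a * b0$lower + c0, tolerance = 1e-9)
      expect_equal(b1$upper, a * b0$upper + c0, tolerance = 1e-9)
    }
  }
})

test_that("the Hampel band resists contamination that inflates the 3-sigma band", {
  set.seed(14)
  # window of 9: the max attainable z-score (8/3 < 3) guarantees masking
  win <- rnorm(9)                # sigma = 1
  win[5] <- 50                   # one 50-sigma outlier
  bh <- band_hampel(win, factor = 3)
  bs <- band_three_sigma(win, factor = 3)
  expect_lt(bh$upper - bh$lower, bs$upper - bs$lower)
  # masking: the non-robust band swallows the outlier, Hampel does not
  expect_true(win[5] > bh$upper)
  expect_true(win[5] < bs$upper)
})

test_that("normal-theory constants recompute to their printed values", {
  k <- normal_consistency_constants()
  v <- setNames(k$value, k$constant)
  expect_equal(unname(v["three_sigma_coverage_pct"]), 99.73, tolerance = 5e-3)
  expect_equal(unname(v["hampel_b"]), 1.4826, tolerance = 5e-5)
  expect_equal(unname(v["iqr_to_sigma"]), 1.35, tolerance = 5e-3)
  expect_equal(unname(v["iqr_factor2_sigma_band"]), 2.7, tolerance = 5e-2)
  expect_identical(unname(v["min_window_three_sigma"]), 11)
})

test_that("threshold spec validates dynamic parameters", {
  expect_error(threshold_spec("three_sigma"),
               class = "permclean_parameter_error") # w3 required
  expect_error(threshold_spec("iqr", w3 = 3),
               class = "permclean_parameter_error") # iqr needs w3 >= 4
  expect_equal(threshold_spec("iqr", w3 = 10)$threshold_factor, 2)
  expect_equal(threshold_spec("hampel", w3 = 10)$threshold_factor, 3)
})
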