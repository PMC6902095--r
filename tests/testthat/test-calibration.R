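test_that("fit_calibration recovers exact log-law points", {
  cal <- fit_calibration(c(1, exp(1), exp(2)), c(10, 12, 14))
  expect_equal(cal$a, 10)
  expect_equal(cal$b, 2)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-9)
  expect_equal(cal$domain, c(1, exp(2)))
  expect_equal(cal$n_standards, 3L)
})

test_that("fit_calibration agrees with a grid-search oracle on noisy standards", {
  set.seed(11)
  for (rep in 1:3) {
    q <- default_standard_contents()
    I <- 50 + 12 * log(q) + rnorm(6, 0, 1.5)
    cal <- fit_calibration(q, I)
    gs <- grid_fit_oracle(q, I)
    expect_equal(cal$a, unname(gs["a"]), tolerance = 1e-3)
    expect_equal(cal$b, unname(gs["b"]), tolerance = 1e-3)
  }
})

test_that("fit_calibration error contracts", {
  expect_error(fit_calibration(c(1, 2), c(5, 6)), "3 usable")
  expect_error(fit_calibration(c(1, 1, 1), c(5, 6, 7)), "distinct")
  expect_error(fit_calibration(c(-1, 2, 4), c(5, 6, 7)), "positive")
  # decreasing intensities: b <= 0 must raise, not warn
  expect_error(fit_calibration(c(1, exp(1), exp(2)), c(14, 12, 10)),
               "non-monotone")
})

test_that("invert_calibration: exact points and bisection oracle", {
  cal <- fit_calibration(c(1, exp(1), exp(2)), c(10, 12, 14))
  expect_equal(invert_calibration(cal, 10)$content, 1)
  expect_equal(invert_calibration(cal, 12)$content, exp(1))
  set.seed(5)
  I <- runif(100, 5, 20)
  got <- invert_calibration(cal, I)$content
  oracle <- vapply(I, function(i) bisect_invert_oracle(cal, i), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
  # extrapolation flagged outside the standards' span, never an error
  expect_true(invert_calibration(cal, 50)$extrapolated)
  expect_false(invert_calibration(cal, 12)$extrapolated)
})

test_that("round trip: fit then invert returns contents to 1e-9", {
  set.seed(3)
  for (rep in 1:5) {
    a <- runif(1, 10, 200); b <- runif(1, 1, 50)
    q <- sort(exp(runif(6, log(2), log(50))))
    cal <- fit_calibration(q, a + b * log(q))
    qq <- exp(seq(log(min(q)), log(max(q)), length.out = 20))
    rec <- invert_calibration(cal, a + b * log(qq))$content
    expect_equal(rec, qq, tolerance = 1e-9)
    expect_false(any(invert_calibration(cal, a + b * log(qq))$extrapolated))
  }
})

test_that("recovered contents are invariant to affine intensity changes", {
  set.seed(9)
  q <- default_standard_contents()
  I <- 30 + 8 * log(q) + rnorm(6, 0, 0.5)
  Is <- 30 + 8 * log(c(7, 15, 33))
  base <- invert_calibration(fit_calibration(q, I), Is)$content
  shift <- invert_calibration(fit_calibration(q, I + 123), Is + 123)$content
  scale <- invert_calibration(fit_calibration(q, I * 2.5), Is * 2.5)$content
  expect_equal(shift, base, tolerance = 1e-9)
  expect_equal(scale, base, tolerance = 1e-9)
})

test_that("quantify_sample aggregates replicates as stated", {
  # curve with I = ln(q): replicate intensities mapping to {19, 20, 21}
  cal <- fit_calibration(c(1, exp(1), exp(2)), c(0, 1, 2))
  r <- quantify_sample(log(c(19, 20, 21)), cal)
  expect_equal(r$content_mean, 20)
  expect_equal(r$relative_sd, 0.05)
  expect_equal(r$content_se, 1 / sqrt(3), tolerance = 1e-6)
  expect_equal(r$n_replicates, 3L)
  # identical replicates
  r2 <- quantify_sample(log(c(20, 20, 20)), cal)
  expect_equal(r2$relative_sd, 0)
  expect_equal(r2$content_se, 0)
  # flag handling
  r3 <- quantify_sample(log(c(19, 20, 21)), cal,
                        exclude = c(FALSE, FALSE, TRUE))
  expect_equal(r3$n_replicates, 2L)
  expect_true(r3$saturated_replicate)
  expect_error(quantify_sample(log(20), cal, exclude = TRUE), "flagged")
})

test_that("first-order error propagation: content CV ~ intensity SD / b", {
  set.seed(21)
  b <- 40; a <- 100; s <- 2
  I <- a + b * log(15) + rnorm(4000, 0, s)
  cal <- fit_calibration(c(2, 10, 50), a + b * log(c(2, 10, 50)))
  rec <- invert_calibration(cal, I)$content
  expect_equal(sd(rec) / mean(rec), s / b, tolerance = 0.05)
})

test_that("content_to_copies mass-fraction arithmetic", {
  expect_equal(content_to_copies(0, 1000, 3.2e9), 0)
  expect_equal(content_to_copies(1000, 3.2e9, 3.2e9), 1)
  expect_equal(content_to_copies(1.55, 13000, 3.2e9), 381.538, tolerance = 1e-3)
  expect_error(content_to_copies(1, -5, 3.2e9), "positive")
})
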