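test_that("make_cohort reproduces requested moments and contracts", {
  spec <- cohort_spec("HC", 401, 22.0, 6.7, with_panss = FALSE)
  co <- make_cohort(spec, seed = 1)
  expect_equal(nrow(co), 401)
  expect_true(all(co$content > 0))
  # sample mean within 3 standard errors of the target
  expect_lt(abs(mean(co$content) - 22.0), 3 * 6.7 / sqrt(401))
  expect_true(all(co$birth_year >= 1935 & co$birth_year <= 2001))
  # degenerate sd: all contents at the mean
  co0 <- make_cohort(cohort_spec("X", 10, 15, 0), seed = 1)
  expect_equal(co0$content, rep(15, 10))
  # determinism
  expect_identical(make_cohort(spec, seed = 5), make_cohort(spec, seed = 5))
  expect_false(identical(make_cohort(spec, seed = 5),
                         make_cohort(spec, seed = 6)))
})

test_that("cohort_spec validates its arguments", {
  expect_error(cohort_spec("X", 0, 10, 1), ">= 1")
  expect_error(cohort_spec("X", 5, 10, -1), "nonnegative")
  expect_error(cohort_spec("X", 5, -10, 1), "positive")
})

test_that("lognormal family matches requested moments at large n", {
  spec <- cohort_spec("X", 20000, 18, 5.9,
                      distribution_family = "lognormal")
  co <- make_cohort(spec, seed = 2)
  expect_equal(mean(co$content), 18, tolerance = 0.01)
  expect_equal(sd(co$content), 5.9, tolerance = 0.05)
})

test_that("PANSS follows the linear model", {
  spec <- cohort_spec("X", 2000, 18, 5.9, panss_beta0 = 120,
                      panss_beta1 = -1, panss_sd = 1e-9)
  co <- make_cohort(spec, seed = 3)
  expect_equal(co$panss, 120 - co$content, tolerance = 1e-6)
  hc <- make_cohort(table2_specs()$HC, seed = 1)
  expect_false("panss" %in% names(hc))
})

test_that("shrinkage generator obeys its law exactly when noiseless", {
  # kappa = 1: follow-up identical to baseline
  t1 <- make_paired_therapy(therapy_spec(n = 50, kappa = 1, eps_sd = 0),
                            seed = 1)
  expect_equal(t1$post, t1$pre)
  # kappa = 0.5, setpoint at the spec mean: exact elementwise law
  sp <- therapy_spec(n = 200, pre_mean = 17, pre_sd = 3,
                     setpoint_mu = 17, kappa = 0.5, eps_sd = 0)
  t2 <- make_paired_therapy(sp, seed = 2)
  expect_equal(t2$post, 17 + 0.5 * (t2$pre - 17), tolerance = 1e-12)
  # CV halves up to the sampling deviation of the baseline mean
  expect_equal(sd(t2$post) / mean(t2$post),
               0.5 * sd(t2$pre) / mean(t2$pre), tolerance = 0.02)
  expect_error(therapy_spec(kappa = 1.2), "kappa")
})

test_that("default therapy world: CV 0.31 shrinks into the 0.13-0.17 band", {
  # closed form: CV_post = sqrt(kappa^2 sd^2 + eps^2) / mu
  sp <- therapy_spec()
  expect_equal(sqrt(sp$kappa^2 * sp$pre_sd^2 + sp$eps_sd^2) / sp$pre_mean,
               0.152, tolerance = 0.01)
  cvs <- vapply(1:20, function(s) {
    tab <- make_paired_therapy(sp, seed = s)
    sd(tab$post) / mean(tab$post)
  }, numeric(1))
  expect_true(all(cvs > 0.11 & cvs < 0.19))
  expect_true(median(cvs) > 0.13 && median(cvs) < 0.17)
})

test_that("brain panel generator honours its spec", {
  sp <- brain_panel_spec(low_sd = 0.5, high_sd = 0.5, tr_sd = 0)
  pan <- make_brain_panel(sp, seed = 4)
  expect_equal(nrow(pan), 8)
  expect_equal(sum(pan$component == "low"), 3)
  # tr exactly linear in satIII when tr_sd = 0
  expect_equal(pan$tr, 60 - pan$satIII, tolerance = 1e-12)
  expect_equal(repeat_correlation(pan$satIII, pan$tr)$pearson_r, -1)
  # tr_slope = 0, tr_sd = 0: constant telomere signal
  pan2 <- make_brain_panel(brain_panel_spec(tr_slope = 0, tr_sd = 0),
                           seed = 4)
  expect_equal(diff(range(pan2$tr)), 0)
  # rDNA tightly around its mean
  pan3 <- make_brain_panel(brain_panel_spec(), seed = 5)
  expect_lt(sd(pan3$rdna) / mean(pan3$rdna), 0.05)
  # degenerate mixture rejected
  expect_error(brain_panel_spec(low_mean = 10, high_mean = 10),
               "degenerate")
  expect_error(brain_panel_spec(n_low = 8), "n_low")
  expect_identical(make_brain_panel(sp, seed = 9),
                   make_brain_panel(sp, seed = 9))
})

test_that("well-separated panel recovers the 3.7x subgroup ratio", {
  sp <- brain_panel_spec(low_mean = 7.3, low_sd = 0.4,
                         high_mean = 26.8, high_sd = 0.8)
  ratios <- vapply(1:10, function(s) {
    pan <- make_brain_panel(sp, seed = s)
    p <- partition_bimodal(pan$satIII)
    p$high_mean / p$low_mean
  }, numeric(1))
  expect_equal(median(ratios), 3.7, tolerance = 0.05)
})
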