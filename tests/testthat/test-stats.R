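test_that("descriptive statistics match hand arithmetic", {
  d <- descriptive(c(10, 20, 30))
  expect_equal(d$mean, 20)
  expect_equal(d$sd, 10)
  expect_equal(d$median, 20)
  expect_equal(d$cv, 0.5)
  dc <- descriptive(rep(7, 5))
  expect_equal(dc$sd, 0)
  expect_equal(dc$cv, 0)
  d1 <- descriptive(42)
  expect_equal(d1$sd, 0)
  expect_error(descriptive(numeric(0)), "empty")
})

test_that("Mann-Whitney exact path: separation and symmetry", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2/20 assignments as extreme
  expect_identical(r$method, "exact")
  expect_false(r$significant)
  # identical samples: p = 1 (ties force the normal path, z = 0)
  r2 <- mann_whitney(c(5, 6, 7, 8, 9, 10, 11, 12, 13),
                     c(5, 6, 7, 8, 9, 10, 11, 12, 13))
  expect_equal(r2$p, 1)
  expect_equal(r2$z, 0)
})

test_that("Mann-Whitney exact p equals the enumeration oracle", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    repeat {
      x <- round(rnorm(n, 0, 5), 3)
      y <- round(rnorm(m, 1, 5), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    got <- mann_whitney(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p, mw_enum_p(x, y), tolerance = 1e-12)
    # symmetry of the two-sided p
    expect_equal(mann_whitney(y, x)$p, got$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(17)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  p0 <- mann_whitney(x, y)$p
  expect_equal(mann_whitney(exp(x), exp(y))$p, p0)
  expect_equal(mann_whitney(x^3, y^3)$p, p0)
  k0 <- abs(ks_two_sample(x, y)$D)
  expect_equal(abs(ks_two_sample(exp(x), exp(y))$D), k0)
})

test_that("KS statistic: separation, identity, sign and scan oracle", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$D, 1)
  r2 <- ks_two_sample(1:5, 1:5)
  expect_equal(r2$D, 0)
  expect_equal(r2$alpha, 1)
  # sign convention: first sample stochastically larger => negative D
  expect_lt(ks_two_sample(c(10, 11, 12), c(1, 2, 3))$D, 0)
  set.seed(19)
  for (rep in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.8)
    got <- ks_two_sample(x, y)
    expect_equal(got$D, ks_scan_D(x, y), tolerance = 1e-12)
  }
})

test_that("KS alpha matches the asymptotic tail used by base R at large n", {
  set.seed(23)
  x <- rnorm(300); y <- rnorm(250, 0.2)
  got <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y))
  expect_equal(abs(got$D), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$alpha, ref$p.value, tolerance = 1e-6)
})

test_that("compare_groups: self-comparison and error contracts", {
  co <- data.frame(group = rep(c("A", "B"), each = 20),
                   content = c(rnorm(20, 10), rnorm(20, 12)))
  self <- compare_groups(rbind(co, co), list(c("A", "A")))
  expect_equal(self$table$p, 1)
  expect_equal(self$table$D, 0)
  expect_error(compare_groups(co, list(c("A", "Z"))), "unknown")
  rep2 <- compare_groups(co, list(c("A", "B")))
  expect_equal(rep2$table$n1, 20)
  expect_true(is.finite(rep2$table$U))
})

test_that("type-I behaviour: same-spec cohorts rarely reach p <= 0.01", {
  spec <- cohort_spec("X", 143, 14.7, 3.0, with_panss = FALSE)
  ps <- vapply(1:100, function(s) {
    a <- make_cohort(spec, seed = 2 * s)
    b <- make_cohort(spec, seed = 2 * s + 1)
    mann_whitney(a$content, b$content)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.90)
})

test_that("stratify_by_birth_year partitions exhaustively at the cut", {
  co <- data.frame(birth_year = c(1989, 1990), content = c(1, 2))
  s <- stratify_by_birth_year(co)
  expect_equal(nrow(s$older), 1)
  expect_equal(nrow(s$younger), 1)
  expect_equal(s$younger$birth_year, 1990)
  co2 <- data.frame(birth_year = rep(1950, 7), content = 1:7)
  s2 <- stratify_by_birth_year(co2)
  expect_equal(c(nrow(s2$older), nrow(s2$younger)), c(7, 0))
  set.seed(29)
  co3 <- data.frame(birth_year = sample(1935:2001, 57, TRUE), content = 0)
  s3 <- stratify_by_birth_year(co3)
  expect_equal(nrow(s3$older) + nrow(s3$younger), 57)
  expect_equal(nrow(s3$younger), sum(co3$birth_year >= 1990))
  expect_error(stratify_by_birth_year(data.frame(birth_year = NA)), "missing")
})

test_that("ecdf_table is a right-continuous step reaching 1", {
  expect_equal(ecdf_table(5), data.frame(value = 5, fraction = 1))
  e <- ecdf_table(c(1, 1, 2))
  expect_equal(e$value, c(1, 2))
  expect_equal(e$fraction, c(2 / 3, 1))
  set.seed(31)
  v <- rnorm(40)
  e2 <- ecdf_table(v)
  # rank/n oracle at each unique point
  expect_equal(e2$fraction, rank(e2$value) * 0 +
                 vapply(e2$value, function(t) sum(v <= t) / 40, numeric(1)))
  expect_equal(utils::tail(e2$fraction, 1), 1)
})
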