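#' Descriptive statistics for a content vector
#'
#' @param values Numeric vector (nonempty).
#' @return List of class `descriptives`: `n`, `mean`, `sd` (sample SD,
#'   divisor `n - 1`; 0 for `n = 1`), `min`, `max`, `median`, `cv`
#'   (`sd/mean`).  Values are never rounded internally; round only when
#'   reporting (CVs are conventionally printed to 2 decimals).
#' @examples
#' descriptive(c(10, 20, 30))
#' @export
descriptive <- function(values) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  structure(
    list(n = n, mean = m, sd = s, min = min(values), max = max(values),
         median = stats::median(values),
         cv = if (m != 0) s / abs(m) else 0),
    class = "descriptives"
  )
}

#' @export
print.descriptives <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.3g, sd = %.3g, range = [%.3g, %.3g], median = %.3g, cv = %.2f\n",
              x$n, x$mean, x$sd, x$min, x$max, x$median, x$cv))
  invisible(x)
}

#' @export
as.data.frame.descriptives <- function(x, ...) {
  data.frame(n = x$n, mean = x$mean, sd = x$sd, min = x$min, max = x$max,
             median = x$median, cv = x$cv)
}

new_test_result <- function(test, p, U = NA_real_, D = NA_real_,
                            alpha = NA_real_, z = NA_real_, method = NA) {
  structure(
    list(test = test, U = U, p = p, D = D, alpha = alpha, z = z,
         method = method, significant = is.finite(p) && p <= 0.01),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  if (x$test == "mann_whitney") {
    cat(sprintf("Mann-Whitney U = %.4g, two-sided p = %.4g (%s)%s\n",
                x$U, x$p, x$method,
                if (x$significant) " *" else ""))
  } else {
    cat(sprintf("Kolmogorov-Smirnov D = %.4g, alpha = %.4g%s\n",
                x$D, x$alpha, if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` is the Mann-Whitney statistic of the first sample (its rank sum
#' minus `n(n+1)/2`), with midranks for ties.  The two-sided p-value is
#' computed by exact enumeration of all rank assignments when
#' `max(n, m) <= 8` and there are no ties, otherwise by the normal
#' approximation with tie-corrected variance and continuity correction.
#' Significance is declared at `p <= 0.01`.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return A `test_result` with fields `U`, `p`, `z` (normal path only),
#'   `method` (`"exact"` or `"normal"`), `significant`.
#' @examples
#' mann_whitney(1:3, 4:6)  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && max(n, m) <= 8L) {
    ## exact null distribution of U by enumeration of rank assignments
    dist <- mw_exact_dist(n, m)
    p_le <- sum(dist$prob[dist$u <= U + 1e-9])
    p_ge <- sum(dist$prob[dist$u >= U - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
    return(new_test_result("mann_whitney", p = p, U = U, method = "exact"))
  }
  mu <- n * m / 2
  N <- n + m
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(new_test_result("mann_whitney", p = 1, U = U, z = 0,
                           method = "normal"))
  }
  dev <- U - mu
  cc <- sign(dev) * 0.5
  z <- if (dev == 0) 0 else (dev - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result("mann_whitney", p = p, U = U, z = z, method = "normal")
}

## exact null distribution of U for sample sizes n, m (no ties)
mw_exact_dist <- function(n, m) {
  combs <- utils::combn(n + m, n)
  u <- colSums(combs) - n * (n + 1) / 2
  tab <- table(u)
  list(u = as.numeric(names(tab)), prob = as.numeric(tab) / ncol(combs))
}

#' Two-sample Kolmogorov-Smirnov statistic with asymptotic significance
#'
#' `D` is the signed value of `F_x - F_y` at the point maximizing
#' `|F_x - F_y|` (first such point in pooled order), so its sign says which
#' sample is stochastically smaller.  `alpha` is the asymptotic Kolmogorov
#' tail probability evaluated at `|D|*sqrt(n*m/(n+m))` — a p-value, despite
#' the traditional "alpha" name in blot-densitometry reports.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return A `test_result` with fields `D`, `alpha`, `p` (equal to
#'   `alpha`), `significant` (`alpha <= 0.01`).
#' @examples
#' ks_two_sample(1:3, 4:6)  # D = 1: complete separation
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n <- length(x); m <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  dif <- Fx - Fy
  i <- which.max(abs(dif))
  D <- dif[i]
  lambda <- abs(D) * sqrt(n * m / (n + m))
  alpha <- kolmogorov_tail(lambda)
  out <- new_test_result("ks_two_sample", p = alpha, D = D, alpha = alpha)
  out$significant <- alpha <= 0.01
  out
}

## Kolmogorov asymptotic tail probability Q(lambda) = 2*sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Pairwise group comparisons on a cohort table
#'
#' For each requested pair of groups, computes both nonparametric tests
#' ([mann_whitney()] and [ks_two_sample()]) on the content values plus
#' [descriptive()] summaries of both groups.
#'
#' @param cohort Cohort `data.frame` with columns `group` and `content`.
#' @param pairs List of length-2 character vectors of group labels.
#' @return List of class `comparison_report`: `table` (one row per pair
#'   with n/mean/sd per group, `U`, `p`, `D`, `alpha`, `significant`) and
#'   `details` (full test and descriptive objects per pair).
#' @examples
#' co <- bind_cohorts(make_cohort(table2_specs()$HC, seed = 1),
#'                    make_cohort(table2_specs()$NH_SZ_Mplus, seed = 2))
#' compare_groups(co, list(c("HC", "NH_SZ_Mplus")))$table
#' @export
compare_groups <- function(cohort, pairs) {
  stopifnot(is.data.frame(cohort), all(c("group", "content") %in% names(cohort)))
  if (is.character(pairs)) pairs <- list(pairs)
  details <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    for (g in pr) {
      if (!any(cohort$group == g)) stop("unknown or empty group: ", g)
    }
    x <- cohort$content[cohort$group == pr[1]]
    y <- cohort$content[cohort$group == pr[2]]
    list(group1 = pr[1], group2 = pr[2],
         mw = mann_whitney(x, y), ks = ks_two_sample(x, y),
         desc1 = descriptive(x), desc2 = descriptive(y))
  })
  table <- do.call(rbind, lapply(details, function(d) {
    data.frame(
      group1 = d$group1, group2 = d$group2,
      n1 = d$desc1$n, mean1 = d$desc1$mean, sd1 = d$desc1$sd,
      n2 = d$desc2$n, mean2 = d$desc2$mean, sd2 = d$desc2$sd,
      U = d$mw$U, p = d$mw$p, D = d$ks$D, alpha = d$ks$alpha,
      significant = d$mw$significant,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(table = table, details = details),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Split a cohort into birth-year strata
#'
#' @param cohort Cohort `data.frame` with a `birth_year` column (no `NA`).
#' @param cut_year First year of the younger stratum (default 1990, i.e.
#'   strata 1935-1989 and 1990-2001).
#' @return List with elements `older` (`birth_year < cut_year`) and
#'   `younger` (`birth_year >= cut_year`); the partition is exhaustive and
#'   disjoint.
#' @export
stratify_by_birth_year <- function(cohort, cut_year = 1990) {
  stopifnot(is.data.frame(cohort), "birth_year" %in% names(cohort))
  if (anyNA(cohort$birth_year)) stop("missing birth years")
  list(older = cohort[cohort$birth_year < cut_year, , drop = FALSE],
       younger = cohort[cohort$birth_year >= cut_year, , drop = FALSE])
}

#' Empirical cumulative distribution table
#'
#' The right-continuous step ECDF as an ordered table of unique values and
#' cumulative fractions (final fraction exactly 1), ready for plotting or
#' CSV export.
#'
#' @param values Numeric vector (nonempty).
#' @return `data.frame` with columns `value` and `fraction`.
#' @examples
#' ecdf_table(c(1, 1, 2))
#' @export
ecdf_table <- function(values) {
  if (!length(values)) stop("empty input")
  v <- sort(unique(values))
  data.frame(value = v,
             fraction = vapply(v, function(t) mean(values <= t), numeric(1)))
}
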