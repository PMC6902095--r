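#' Paired pre/post therapy analysis
#'
#' Quantifies regression toward a setpoint in paired repeat-content
#' measurements taken before and after a course of therapy: the coefficient
#' of variation of each time point, the OLS slope of the change
#' `(post - pre)` on baseline (a slope of `kappa - 1` under the shrinkage
#' model, so `kappa_hat = 1 + slope`), mean changes in the low- and
#' high-baseline windows, and unpaired two-sample tests of the overall
#' distributions (the customary report when the question is whether
#' treatment shifts the distribution at all).
#'
#' @param pre,post Equal-length paired content vectors (pg/ng DNA),
#'   `n >= 3`.
#' @param low_max Upper edge of the low-baseline window (default 12 pg/ng:
#'   baselines `<= low_max`).
#' @param high_min Lower edge of the high-baseline window (default
#'   25 pg/ng: baselines `>= high_min`).
#' @return List of class `therapy_report`: `n`, `cv_pre`, `cv_post`,
#'   `delta_on_pre_slope`, `kappa_hat`, `low_baseline_delta_mean`,
#'   `high_baseline_delta_mean` (`NA` when the window is empty), `mw` and
#'   `ks` ([mann_whitney()] / [ks_two_sample()] of pre vs post).
#' @examples
#' tab <- make_paired_therapy(therapy_spec(), seed = 1)
#' rep <- paired_therapy_analysis(tab$pre, tab$post)
#' c(rep$cv_pre, rep$cv_post)
#' @export
paired_therapy_analysis <- function(pre, post, low_max = 12, high_min = 25) {
  if (length(pre) != length(post)) stop("pre/post length mismatch")
  if (length(pre) < 3) stop("need n >= 3 pairs")
  delta <- post - pre
  slope <- unname(stats::coef(stats::lm(delta ~ pre))[2])
  low <- pre <= low_max
  high <- pre >= high_min
  structure(
    list(
      n = length(pre),
      cv_pre = stats::sd(pre) / mean(pre),
      cv_post = stats::sd(post) / mean(post),
      delta_on_pre_slope = slope,
      kappa_hat = 1 + slope,
      low_baseline_delta_mean = if (any(low)) mean(delta[low]) else NA_real_,
      high_baseline_delta_mean = if (any(high)) mean(delta[high]) else NA_real_,
      mw = mann_whitney(pre, post),
      ks = ks_two_sample(pre, post)
    ),
    class = "therapy_report"
  )
}

#' @export
print.therapy_report <- function(x, ...) {
  cat(sprintf("Paired therapy analysis (n = %d)\n", x$n))
  cat(sprintf("  CV before %.2f -> after %.2f\n", x$cv_pre, x$cv_post))
  cat(sprintf("  slope of change on baseline %.3f (kappa_hat = %.3f)\n",
              x$delta_on_pre_slope, x$kappa_hat))
  cat(sprintf("  mean change, low baselines: %+.2f; high baselines: %+.2f\n",
              x$low_baseline_delta_mean, x$high_baseline_delta_mean))
  print(x$mw); print(x$ks)
  invisible(x)
}

#' Association between repeat content and a severity score
#'
#' Linear regression of the severity score (PANSS) on content, the Pearson
#' correlation, and a dichotomized comparison: subgroup I has content below
#' the threshold, subgroup II at or above it, with a [mann_whitney()] test
#' between subgroup scores.
#'
#' @param content Repeat contents (pg/ng DNA), not all equal, `n >= 3`.
#' @param panss Paired severity scores.
#' @param threshold Dichotomization threshold in pg/ng DNA (default 20).
#' @return List of class `panss_report`: `ols_slope`, `ols_intercept`,
#'   `pearson_r`, `n`, `threshold`, `subgroup_I_desc`, `subgroup_II_desc`
#'   ([descriptive()] of the scores in each subgroup, `NULL` if empty) and
#'   `mw`.
#' @examples
#' co <- make_cohort(table2_specs()$SZ_all, seed = 1)
#' rep <- panss_association(co$content, co$panss)
#' rep$ols_slope
#' @export
panss_association <- function(content, panss, threshold = 20) {
  if (length(content) != length(panss)) stop("length mismatch")
  if (length(content) < 3) stop("need n >= 3")
  if (stats::sd(content) == 0) stop("zero variance in content")
  fit <- stats::lm(panss ~ content)
  lo <- content < threshold
  hi <- !lo
  mw <- if (any(lo) && any(hi)) mann_whitney(panss[lo], panss[hi]) else NULL
  structure(
    list(
      n = length(content),
      threshold = threshold,
      ols_slope = unname(stats::coef(fit)[2]),
      ols_intercept = unname(stats::coef(fit)[1]),
      pearson_r = stats::cor(content, panss),
      subgroup_I_desc = if (any(lo)) descriptive(panss[lo]) else NULL,
      subgroup_II_desc = if (any(hi)) descriptive(panss[hi]) else NULL,
      mw = mw
    ),
    class = "panss_report"
  )
}

#' @export
print.panss_report <- function(x, ...) {
  cat(sprintf("Severity association (n = %d): PANSS = %.2f %+.3f * content, r = %.3f\n",
              x$n, x$ols_intercept, x$ols_slope, x$pearson_r))
  if (!is.null(x$subgroup_I_desc)) {
    cat(sprintf("  subgroup I  (< %g pg/ng): mean PANSS %.1f (n = %d)\n",
                x$threshold, x$subgroup_I_desc$mean, x$subgroup_I_desc$n))
  }
  if (!is.null(x$subgroup_II_desc)) {
    cat(sprintf("  subgroup II (>= %g pg/ng): mean PANSS %.1f (n = %d)\n",
                x$threshold, x$subgroup_II_desc$mean, x$subgroup_II_desc$n))
  }
  if (!is.null(x$mw)) print(x$mw)
  invisible(x)
}
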