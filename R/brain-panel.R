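#' Optimal two-group partition of a 1-D sample (two-means threshold scan)
#'
#' Finds the two-subset partition minimizing the total within-subset sum of
#' squares by scanning all `n - 1` thresholds between consecutive order
#' statistics (the unrestricted optimum over all 2-subset partitions is
#' always contiguous in sorted order, so the scan is exhaustive).  Also
#' reports a [mann_whitney()] p-value between the two subgroups — at
#' brain-panel sample sizes this is descriptive, not confirmatory.
#'
#' @param values Numeric vector, `n >= 4`, not all equal.
#' @return List of class `bimodal_partition`: `labels` (`"low"`/`"high"`
#'   per input element, input order), `low_mean`, `high_mean`
#'   (`low_mean < high_mean`), `ratio` (`high_mean/low_mean`), `threshold`
#'   (midpoint between the boundary order statistics), `within_ss`, `n_low`,
#'   `n_high`, `mw_p`.
#' @examples
#' p <- partition_bimodal(c(5.0, 7.4, 9.5, 21, 25, 27, 29, 32))
#' c(p$low_mean, p$high_mean, p$ratio)
#' @export
partition_bimodal <- function(values) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values")
  if (length(unique(values)) == 1L) stop("all values equal: no separation")
  o <- order(values)
  s <- values[o]
  wss <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  tot <- vapply(seq_len(n - 1), function(k) {
    wss(s[seq_len(k)]) + wss(s[(k + 1):n])
  }, numeric(1))
  k <- which.min(tot)
  labels <- character(n)
  labels[o[seq_len(k)]] <- "low"
  labels[o[(k + 1):n]] <- "high"
  low <- values[labels == "low"]; high <- values[labels == "high"]
  structure(
    list(labels = labels,
         low_mean = mean(low), high_mean = mean(high),
         ratio = mean(high) / mean(low),
         threshold = (s[k] + s[k + 1]) / 2,
         within_ss = tot[k], n_low = k, n_high = n - k,
         mw_p = mann_whitney(low, high)$p),
    class = "bimodal_partition"
  )
}

#' @export
print.bimodal_partition <- function(x, ...) {
  cat(sprintf(
    "Bimodal partition: low %.3g (n = %d) vs high %.3g (n = %d); ratio %.1f; threshold %.3g; MW p = %.3g\n",
    x$low_mean, x$n_low, x$high_mean, x$n_high, x$ratio, x$threshold, x$mw_p))
  invisible(x)
}

#' Constancy check on a repeat-content vector
#'
#' Declares a repeat "constant across regions" when its coefficient of
#' variation does not exceed a relative tolerance; used for the ribosomal
#' repeat, whose copy number is expected stable within one individual.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param rel_tol Maximum CV to pass (default 0.05).
#' @return List: `pass`, `cv`, `mean`, `sd`, `rel_tol`.
#' @examples
#' constancy_check(rnorm(8, 381, 7))
#' @export
constancy_check <- function(values, rel_tol = 0.05) {
  if (length(values) < 2) stop("need at least 2 values")
  d <- descriptive(values)
  list(pass = d$cv <= rel_tol, cv = d$cv, mean = d$mean, sd = d$sd,
       rel_tol = rel_tol)
}

#' Correlation between two repeat-content vectors
#'
#' @param x,y Aligned numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return List: `pearson_r`, `spearman_rho`, `n`.
#' @examples
#' pan <- make_brain_panel(brain_panel_spec(), seed = 1)
#' repeat_correlation(pan$satIII, pan$tr)
#' @export
repeat_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  list(pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       n = length(x))
}

#' Full brain-panel report
#'
#' Convenience wrapper chaining [partition_bimodal()] on the satellite
#' repeat, [constancy_check()] on the ribosomal repeat and
#' [repeat_correlation()] between satellite and telomere repeats.
#'
#' @param panel `data.frame` with columns `satIII`, `rdna`, `tr` (one row
#'   per region), as produced by [make_brain_panel()] or read from CSV.
#' @param rdna_rel_tol Tolerance for the ribosomal constancy check.
#' @return List of class `brain_panel_report`: `partition`, `rdna`,
#'   `correlation`, `n_regions`.
#' @export
brain_panel_report <- function(panel, rdna_rel_tol = 0.05) {
  stopifnot(all(c("satIII", "rdna", "tr") %in% names(panel)))
  structure(
    list(partition = partition_bimodal(panel$satIII),
         rdna = constancy_check(panel$rdna, rdna_rel_tol),
         correlation = repeat_correlation(panel$satIII, panel$tr),
         n_regions = nrow(panel)),
    class = "brain_panel_report"
  )
}

#' @export
print.brain_panel_report <- function(x, ...) {
  cat(sprintf("Brain panel, %d regions\n", x$n_regions))
  print(x$partition)
  cat(sprintf("  rDNA: mean %.1f, cv %.3f -> %s (tol %.2f)\n",
              x$rdna$mean, x$rdna$cv, if (x$rdna$pass) "constant" else "variable",
              x$rdna$rel_tol))
  cat(sprintf("  satIII-TR correlation: r = %.3f, rho = %.3f\n",
              x$correlation$pearson_r, x$correlation$spearman_rho))
  invisible(x)
}
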