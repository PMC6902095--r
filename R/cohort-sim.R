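#' Specification of a synthetic cohort
#'
#' Describes one subject group: the distribution of repeat content
#' (pg/ng DNA), the birth-year window, and an optional linear model tying
#' the PANSS severity score to content
#' (`PANSS = beta0 + beta1*content + eps`).
#'
#' @param group_label Group name, e.g. `"HC"` or `"NH_SZ_Mplus"`.
#' @param n Number of subjects (>= 1).
#' @param mean_content,sd_content Content moments in pg/ng DNA.
#' @param distribution_family `"normal"` (clipped below at 1 pg/ng) or
#'   `"lognormal"` (moment-matched).
#' @param birth_year_range Inclusive integer range of birth years.
#' @param panss_beta0,panss_beta1,panss_sd Linear PANSS model; `beta1 < 0`
#'   encodes the observed weak negative severity-content association.
#' @param with_panss Generate a PANSS column? (healthy controls have none).
#' @return An object of class `cohort_spec`.
#' @seealso [make_cohort()], [table2_specs()]
#' @export
cohort_spec <- function(group_label, n, mean_content, sd_content,
                        distribution_family = c("normal", "lognormal"),
                        birth_year_range = c(1935, 2001),
                        panss_beta0 = 120, panss_beta1 = -1, panss_sd = 25,
                        with_panss = TRUE) {
  distribution_family <- match.arg(distribution_family)
  if (n < 1) stop("n must be >= 1")
  if (sd_content < 0) stop("sd_content must be nonnegative")
  if (mean_content <= 0) stop("mean_content must be positive")
  stopifnot(length(birth_year_range) == 2L,
            birth_year_range[2] >= birth_year_range[1])
  structure(
    list(group_label = group_label, n = as.integer(n),
         mean_content = mean_content, sd_content = sd_content,
         distribution_family = distribution_family,
         birth_year_range = as.integer(birth_year_range),
         panss_beta0 = panss_beta0, panss_beta1 = panss_beta1,
         panss_sd = panss_sd, with_panss = isTRUE(with_panss)),
    class = "cohort_spec"
  )
}

#' Reference cohort specifications at the published group moments
#'
#' The six groups of the motivating leukocyte study with their reported
#' sample sizes and content moments (mean, SD in pg/ng DNA): healthy
#' controls 401 / 22.0 / 6.7; all patients 840 / 18.0 / 5.9; drug-naive
#' patients 283 / 17.0 / 5.9; medicated patients 271 / 18.4 / 5.8;
#' hypoxia-history medicated patients 143 / 22.7 / 5.4; no-hypoxia
#' medicated patients 143 / 14.7 / 3.0.
#'
#' @param distribution_family Passed to every [cohort_spec()].
#' @return Named list of `cohort_spec` objects with names `HC`, `SZ_all`,
#'   `SZ_Mminus`, `SZ_Mplus`, `H_SZ_Mplus`, `NH_SZ_Mplus`.
#' @export
table2_specs <- function(distribution_family = "normal") {
  rows <- list(
    HC          = list(n = 401, mean = 22.0, sd = 6.7, panss = FALSE),
    SZ_all      = list(n = 840, mean = 18.0, sd = 5.9, panss = TRUE),
    SZ_Mminus   = list(n = 283, mean = 17.0, sd = 5.9, panss = TRUE),
    SZ_Mplus    = list(n = 271, mean = 18.4, sd = 5.8, panss = TRUE),
    H_SZ_Mplus  = list(n = 143, mean = 22.7, sd = 5.4, panss = TRUE),
    NH_SZ_Mplus = list(n = 143, mean = 14.7, sd = 3.0, panss = TRUE)
  )
  out <- lapply(names(rows), function(g) {
    r <- rows[[g]]
    cohort_spec(g, r$n, r$mean, r$sd,
                distribution_family = distribution_family,
                with_panss = r$panss)
  })
  stats::setNames(out, names(rows))
}

#' Generate a synthetic cohort table
#'
#' Contents are drawn from the spec's distribution family and clipped below
#' at 1 pg/ng (clipping is statistically negligible at the published
#' moments, whose minima are >= 6); birth years are uniform over the range;
#' PANSS follows the linear model when requested.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; same seed, same table.
#' @return `data.frame` with columns `subject_id`, `group`, `birth_year`,
#'   `content` and (if `with_panss`) `panss`.
#' @examples
#' head(make_cohort(table2_specs()$HC, seed = 1))
#' @export
make_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    content <- switch(spec$distribution_family,
      normal = stats::rnorm(n, spec$mean_content, spec$sd_content),
      lognormal = {
        cv2 <- (spec$sd_content / spec$mean_content)^2
        sdlog <- sqrt(log(1 + cv2))
        meanlog <- log(spec$mean_content) - sdlog^2 / 2
        stats::rlnorm(n, meanlog, sdlog)
      }
    )
    content <- pmax(content, 1)
    yr <- spec$birth_year_range
    out <- data.frame(
      subject_id = sprintf("%s_%04d", spec$group_label, seq_len(n)),
      group = spec$group_label,
      birth_year = sample(seq(yr[1], yr[2]), n, replace = TRUE),
      content = content,
      stringsAsFactors = FALSE
    )
    if (spec$with_panss) {
      out$panss <- spec$panss_beta0 + spec$panss_beta1 * content +
        stats::rnorm(n, 0, spec$panss_sd)
    }
    out
  })
}

#' Bind several cohorts into one table
#'
#' @param ... Cohort tables from [make_cohort()] (or a single list of them).
#' @return Row-bound `data.frame` with a union of columns.
#' @export
bind_cohorts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.data.frame(xs[[1]])) {
    xs <- xs[[1]]
  }
  cols <- unique(unlist(lapply(xs, names)))
  do.call(rbind, lapply(xs, function(x) {
    for (cn in setdiff(cols, names(x))) x[[cn]] <- NA
    x[, cols]
  }))
}

#' Specification of a paired pre/post therapy experiment
#'
#' Follow-up contents shrink toward a setpoint:
#' `post = setpoint_mu + kappa*(pre - setpoint_mu) + eps`,
#' `eps ~ N(0, eps_sd)`.  With `kappa < 1` this is regression toward the
#' setpoint: subjects with low baselines rise, subjects with high baselines
#' fall, and (for `setpoint_mu = pre_mean`, small `eps_sd`) the follow-up
#' CV is about `kappa` times the baseline CV.
#'
#' Defaults emulate the published month-of-antipsychotics experiment:
#' 93 patients, baseline CV 0.31 (mean 17, SD 5.27), `kappa = 0.45` and
#' `eps_sd = 1`, giving a follow-up CV near 0.15.
#'
#' @param n Number of subject pairs.
#' @param pre_mean,pre_sd Baseline content distribution (normal, clipped at
#'   1 pg/ng).
#' @param setpoint_mu Content toward which follow-up shrinks (default
#'   `pre_mean`).
#' @param kappa Retained fraction of the baseline deviation, in `[0, 1]`.
#' @param eps_sd Residual SD of the follow-up.
#' @return Object of class `therapy_spec`.
#' @export
therapy_spec <- function(n = 93, pre_mean = 17, pre_sd = 0.31 * 17,
                         setpoint_mu = pre_mean, kappa = 0.45, eps_sd = 1) {
  if (n < 1) stop("n must be >= 1")
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (pre_sd < 0 || eps_sd < 0) stop("SDs must be nonnegative")
  structure(
    list(n = as.integer(n), pre_mean = pre_mean, pre_sd = pre_sd,
         setpoint_mu = setpoint_mu, kappa = kappa, eps_sd = eps_sd),
    class = "therapy_spec"
  )
}

#' Generate paired pre/post contents under the shrinkage model
#'
#' @param spec A [therapy_spec()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `subject_id`, `pre`, `post`
#'   (pg/ng DNA).
#' @examples
#' tab <- make_paired_therapy(therapy_spec(), seed = 1)
#' sd(tab$post) / mean(tab$post)  # ~ half the baseline CV
#' @export
make_paired_therapy <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "therapy_spec"))
  with_seed(seed, {
    pre <- pmax(stats::rnorm(spec$n, spec$pre_mean, spec$pre_sd), 1)
    post <- spec$setpoint_mu + spec$kappa * (pre - spec$setpoint_mu)
    if (spec$eps_sd > 0) post <- post + stats::rnorm(spec$n, 0, spec$eps_sd)
    data.frame(
      subject_id = sprintf("P%03d", seq_len(spec$n)),
      pre = pre, post = pmax(post, 1),
      stringsAsFactors = FALSE
    )
  })
}

#' Specification of a multi-repeat brain panel
#'
#' Per-region contents of three tandem repeats in one brain: a bimodal
#' satellite III mixture (`n_low` regions around `low_mean`, the rest
#' around `high_mean`), a tightly constant ribosomal repeat, and a telomere
#' repeat decreasing linearly in satellite content.
#'
#' Defaults reproduce the published eight-region panel: a low subgroup of
#' 3 regions at 7.3 +/- 2.5 pg/ng, a high subgroup at 26.8 +/- 4.8 pg/ng
#' (ratio 3.7), rDNA at 381 +/- 7 copies, and an anti-correlated telomere
#' repeat.
#'
#' @param n_regions Number of brain regions (default 8).
#' @param n_low Regions in the low-content subgroup (`1 <= n_low <
#'   n_regions`).
#' @param low_mean,low_sd,high_mean,high_sd Mixture components, pg/ng DNA;
#'   `high_mean` must exceed `low_mean`.
#' @param rdna_copies_mean,rdna_copies_sd Ribosomal repeat copies per
#'   genome.
#' @param tr_intercept,tr_slope,tr_sd Telomere-repeat linear model
#'   `tr = intercept + slope*satIII + eps`; `tr_slope` should be negative.
#' @return Object of class `brain_panel_spec`.
#' @export
brain_panel_spec <- function(n_regions = 8, n_low = 3,
                             low_mean = 7.3, low_sd = 2.5,
                             high_mean = 26.8, high_sd = 4.8,
                             rdna_copies_mean = 381, rdna_copies_sd = 7,
                             tr_intercept = 60, tr_slope = -1, tr_sd = 5) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (n_low < 1 || n_low >= n_regions) stop("need 1 <= n_low < n_regions")
  if (high_mean <= low_mean) {
    stop("degenerate mixture: high_mean must exceed low_mean")
  }
  if (any(c(low_sd, high_sd, rdna_copies_sd, tr_sd) < 0)) {
    stop("SDs must be nonnegative")
  }
  structure(
    list(n_regions = as.integer(n_regions), n_low = as.integer(n_low),
         low_mean = low_mean, low_sd = low_sd,
         high_mean = high_mean, high_sd = high_sd,
         rdna_copies_mean = rdna_copies_mean,
         rdna_copies_sd = rdna_copies_sd,
         tr_intercept = tr_intercept, tr_slope = tr_slope, tr_sd = tr_sd),
    class = "brain_panel_spec"
  )
}

#' Generate a synthetic multi-repeat brain panel
#'
#' @param spec A [brain_panel_spec()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `region`, `satIII` (pg/ng DNA), `rdna`
#'   (copies per genome), `tr` (telomere-repeat content) and the true
#'   mixture component `component` (`"low"`/`"high"`); the low regions are
#'   a random subset.
#' @examples
#' make_brain_panel(brain_panel_spec(), seed = 1)
#' @export
make_brain_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "brain_panel_spec"))
  with_seed(seed, {
    n <- spec$n_regions
    low_idx <- sort(sample(n, spec$n_low))
    comp <- ifelse(seq_len(n) %in% low_idx, "low", "high")
    sat <- ifelse(comp == "low",
                  stats::rnorm(n, spec$low_mean, spec$low_sd),
                  stats::rnorm(n, spec$high_mean, spec$high_sd))
    sat <- pmax(sat, 1)
    rdna <- stats::rnorm(n, spec$rdna_copies_mean, spec$rdna_copies_sd)
    tr <- spec$tr_intercept + spec$tr_slope * sat
    if (spec$tr_sd > 0) tr <- tr + stats::rnorm(n, 0, spec$tr_sd)
    data.frame(
      region = sprintf("region_%d", seq_len(n)),
      satIII = sat, rdna = rdna, tr = tr, component = comp,
      stringsAsFactors = FALSE
    )
  })
}
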