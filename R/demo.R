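#' Default run configuration
#'
#' The configuration is a nested list mirroring the stages of the pipeline;
#' [read_config()] validates user JSON against this schema strictly
#' (unknown keys are errors).  Defaults encode the assay's stated
#' constants: 50 ng per spot in triplicate, six calibration standards, a
#' dichotomization threshold of 20 pg/ng, significance at p <= 0.01, and
#' reporting rounding of 2 decimals for CVs and 1 for contents and ratios.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 20191122,
    membrane = list(
      n_samples = 20,
      content_range = c(6, 40),
      standard_contents = default_standard_contents(),
      signal = list(intercept_a = 10000, slope_b = 2000, q_ref = 1,
                    saturation_level = 1e6, background_level = 500),
      noise = list(assay_cv = 0.05, extraction_cv = 0, pixel_sd = 2,
                   gradient_amplitude = 0),
      radius = 8, pitch = 26, margin = 20, n_replicates = 3,
      bit_depth = 16, quantize = TRUE
    ),
    cohorts = list(
      distribution_family = "normal",
      pairs = list(c("HC", "SZ_Mminus"), c("HC", "SZ_Mplus"),
                   c("HC", "H_SZ_Mplus"), c("HC", "NH_SZ_Mplus"),
                   c("H_SZ_Mplus", "NH_SZ_Mplus"),
                   c("SZ_Mminus", "SZ_Mplus")),
      cut_year = 1990
    ),
    therapy = list(n = 93, pre_mean = 17, pre_sd = 5.27, setpoint_mu = 17,
                   kappa = 0.45, eps_sd = 1, low_max = 12, high_min = 25),
    panss = list(threshold = 20),
    brain = list(n_regions = 8, n_low = 3, low_mean = 7.3, low_sd = 2.5,
                 high_mean = 26.8, high_sd = 4.8,
                 rdna_copies_mean = 381, rdna_copies_sd = 7,
                 tr_intercept = 60, tr_slope = -1, tr_sd = 5),
    rounding = list(cv = 2, content = 1, ratio = 1)
  )
}

#' Read and validate a JSON run configuration
#'
#' User files may specify any subset of keys; missing keys take defaults,
#' unknown keys raise an error (strict schema).
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg, user, "config")
}

merge_config <- function(def, user, where) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown config key(s) under ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    def[[k]] <- if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      merge_config(def[[k]], user[[k]], paste(where, k, sep = "."))
    } else {
      user[[k]]
    }
  }
  def
}

#' Run the full synthetic demonstration pipeline
#'
#' Chains every stage on synthetic data: membrane simulation,
#' densitometry, calibration and quantification, cohort generation and
#' pairwise comparisons with birth-year stratified ECDF exports, paired
#' therapy analysis, severity-score association, and the brain panel.
#' Writes images, CSV tables, JSON reports and PDF figures (ranked
#' contents; stratified ECDFs; ranked paired pre/post; telomere vs
#' satellite scatter) into `out_dir`, plus a `manifest.json` listing every
#' file with its MD5 checksum, the seed and a hash of the configuration.
#' Deterministic: the same config and seed give identical manifests.
#'
#' @param config Configuration list from [read_config()] /
#'   [default_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_full_demo <- function(config = default_config(), out_dir, quiet = FALSE) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  pth <- function(f) file.path(out_dir, f)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  ## 1. membrane -> densitometry -> calibration
  mc <- config$membrane
  say("simulating membrane ...")
  lay <- spot_layout_grid(mc$n_samples,
                          standard_contents = mc$standard_contents,
                          radius = mc$radius, pitch = mc$pitch,
                          margin = mc$margin, n_replicates = mc$n_replicates)
  truec <- with_seed(derive_seed(seed, 1), exp(stats::runif(
    mc$n_samples, log(mc$content_range[1]), log(mc$content_range[2]))))
  names(truec) <- unique(lay$sample_id[lay$role == "sample_replicate"])
  sm <- do.call(signal_model, mc$signal)
  nm <- do.call(noise_model, mc$noise)
  mb <- make_membrane(lay, truec, sm, nm, seed = derive_seed(seed, 2),
                      bit_depth = mc$bit_depth,
                      quantize = isTRUE(mc$quantize))
  add(write_membrane_image(mb, pth("membrane.pgm")))
  add(write_layout_csv(lay, pth("layout.csv")))
  add(write_truth_csv(mb$truth, pth("truth.csv")))
  meas <- measure_membrane(mb)
  add(write_measurements_csv(meas, pth("measurements.csv")))
  mq <- quantify_membrane(meas)
  add(write_json_report(mq$curve, pth("calibration.json")))
  utils::write.csv(mq$samples, pth("sample_quant.csv"), row.names = FALSE)
  add(pth("sample_quant.csv"))

  fig_ranked <- pth("fig_ranked_contents.pdf")
  grDevices::pdf(fig_ranked, width = 6, height = 4)
  ord <- order(mq$samples$content_mean)
  graphics::plot(seq_along(ord), mq$samples$content_mean[ord], pch = 19,
                 xlab = "sample rank", ylab = "content (pg/ng DNA)",
                 main = "Recovered contents, ranked")
  se_ok <- which(mq$samples$content_se[ord] > 0)
  if (length(se_ok)) {
    graphics::arrows(
      se_ok, mq$samples$content_mean[ord][se_ok] -
        mq$samples$content_se[ord][se_ok],
      se_ok, mq$samples$content_mean[ord][se_ok] +
        mq$samples$content_se[ord][se_ok],
      angle = 90, code = 3, length = 0.02)
  }
  grDevices::dev.off()
  add(fig_ranked)

  ## 2. cohorts, comparisons, stratified ECDFs
  say("generating cohorts and comparisons ...")
  specs <- table2_specs(config$cohorts$distribution_family)
  cohorts <- lapply(seq_along(specs), function(i) {
    make_cohort(specs[[i]], seed = derive_seed(seed, 10 + i))
  })
  cohort <- bind_cohorts(cohorts)
  utils::write.csv(cohort, pth("cohort.csv"), row.names = FALSE)
  add(pth("cohort.csv"))
  pairs <- config$cohorts$pairs
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  cmp <- compare_groups(cohort, pairs)
  add(write_json_report(cmp$table, pth("comparisons.json")))

  strat <- stratify_by_birth_year(cohort, config$cohorts$cut_year)
  fig_ecdf <- pth("fig_ecdf.pdf")
  grDevices::pdf(fig_ecdf, width = 6, height = 4)
  graphics::plot(NULL, xlim = range(cohort$content), ylim = c(0, 1),
                 xlab = "content (pg/ng DNA)", ylab = "cumulative fraction",
                 main = "Cumulative distributions by group")
  gs <- unique(cohort$group)
  for (i in seq_along(gs)) {
    et <- ecdf_table(cohort$content[cohort$group == gs[i]])
    graphics::lines(stats::stepfun(et$value, c(0, et$fraction)), col = i,
                    do.points = FALSE)
    utils::write.csv(et, pth(sprintf("ecdf_%s.csv", gs[i])),
                     row.names = FALSE)
    add(pth(sprintf("ecdf_%s.csv", gs[i])))
  }
  graphics::legend("bottomright", legend = gs, col = seq_along(gs), lty = 1,
                   cex = 0.7)
  grDevices::dev.off()
  add(fig_ecdf)
  for (nm2 in names(strat)) {
    utils::write.csv(strat[[nm2]], pth(sprintf("cohort_%s.csv", nm2)),
                     row.names = FALSE)
    add(pth(sprintf("cohort_%s.csv", nm2)))
  }

  ## 3. paired therapy
  say("paired therapy analysis ...")
  tc <- config$therapy
  tsp <- therapy_spec(tc$n, tc$pre_mean, tc$pre_sd, tc$setpoint_mu,
                      tc$kappa, tc$eps_sd)
  ttab <- make_paired_therapy(tsp, seed = derive_seed(seed, 30))
  utils::write.csv(ttab, pth("therapy.csv"), row.names = FALSE)
  add(pth("therapy.csv"))
  trep <- paired_therapy_analysis(ttab$pre, ttab$post,
                                  low_max = tc$low_max,
                                  high_min = tc$high_min)
  add(write_json_report(therapy_report_list(trep), pth("therapy_report.json")))
  fig_ther <- pth("fig_therapy.pdf")
  grDevices::pdf(fig_ther, width = 6, height = 4)
  ordt <- order(ttab$pre)
  graphics::plot(seq_along(ordt), ttab$pre[ordt], pch = 19, cex = 0.6,
                 xlab = "patient rank by baseline",
                 ylab = "content (pg/ng DNA)",
                 main = "Paired contents before/after therapy")
  graphics::points(seq_along(ordt), ttab$post[ordt], pch = 1, cex = 0.6,
                   col = 2)
  graphics::legend("topleft", c("before", "after"), pch = c(19, 1),
                   col = c(1, 2))
  grDevices::dev.off()
  add(fig_ther)

  ## 4. severity association
  say("severity association ...")
  sz <- cohort[cohort$group == "SZ_all", ]
  prep <- panss_association(sz$content, sz$panss,
                            threshold = config$panss$threshold)
  add(write_json_report(panss_report_list(prep), pth("panss_report.json")))

  ## 5. brain panel
  say("brain panel ...")
  bsp <- do.call(brain_panel_spec, config$brain)
  panel <- make_brain_panel(bsp, seed = derive_seed(seed, 40))
  utils::write.csv(panel, pth("brain_panel.csv"), row.names = FALSE)
  add(pth("brain_panel.csv"))
  brep <- brain_panel_report(panel)
  add(write_json_report(brain_report_list(brep), pth("brain_report.json")))
  fig_tr <- pth("fig_tr_vs_satIII.pdf")
  grDevices::pdf(fig_tr, width = 5, height = 4)
  graphics::plot(panel$satIII, panel$tr, pch = 19,
                 xlab = "satellite III (pg/ng DNA)",
                 ylab = "telomere repeat (a.u.)",
                 main = "Telomere repeat vs satellite III")
  graphics::abline(stats::lm(tr ~ satIII, data = panel), lty = 2)
  grDevices::dev.off()
  add(fig_tr)

  ## manifest
  manifest <- list(
    seed = seed,
    config_hash = unname(config_hash(config)),
    files = data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  tools::md5sum(tmp)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

## flat, JSON-friendly views of the report objects
therapy_report_list <- function(x) {
  list(n = x$n, cv_pre = x$cv_pre, cv_post = x$cv_post,
       delta_on_pre_slope = x$delta_on_pre_slope, kappa_hat = x$kappa_hat,
       low_baseline_delta_mean = x$low_baseline_delta_mean,
       high_baseline_delta_mean = x$high_baseline_delta_mean,
       mw_U = x$mw$U, mw_p = x$mw$p, ks_D = x$ks$D, ks_alpha = x$ks$alpha)
}

panss_report_list <- function(x) {
  list(n = x$n, threshold = x$threshold, ols_slope = x$ols_slope,
       ols_intercept = x$ols_intercept, pearson_r = x$pearson_r,
       subgroup_I_mean = if (!is.null(x$subgroup_I_desc)) x$subgroup_I_desc$mean else NA,
       subgroup_II_mean = if (!is.null(x$subgroup_II_desc)) x$subgroup_II_desc$mean else NA,
       mw_p = if (!is.null(x$mw)) x$mw$p else NA)
}

brain_report_list <- function(x) {
  list(n_regions = x$n_regions,
       low_mean = x$partition$low_mean, high_mean = x$partition$high_mean,
       ratio = x$partition$ratio, n_low = x$partition$n_low,
       mw_p = x$partition$mw_p,
       rdna_mean = x$rdna$mean, rdna_cv = x$rdna$cv,
       rdna_constant = x$rdna$pass,
       satIII_tr_pearson_r = x$correlation$pearson_r,
       satIII_tr_spearman_rho = x$correlation$spearman_rho)
}
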