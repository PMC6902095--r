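#' Fit the logarithmic standard curve
#'
#' Ordinary least squares of background-corrected standard intensities on
#' log content: `I = a + b*ln(q/q_ref)`.  Each standard is itself a spot
#' average, so the fit is unweighted.  A non-positive slope means the
#' calibration is not monotone increasing and is an error, not a warning.
#'
#' @param contents Known contents of the standards (pg/ng DNA, positive,
#'   at least 3 distinct values).
#' @param intensities Background-corrected integral intensities, same length.
#' @param q_ref Reference content (default 1 pg/ng).
#' @return An object of class `calibration_curve` with fields `a`, `b`,
#'   `q_ref`, `residual_sd`, `domain` (content range spanned by the
#'   standards) and `n_standards`.
#' @examples
#' cal <- fit_calibration(c(1, exp(1), exp(2)), c(10, 12, 14))
#' cal$a; cal$b
#' @export
fit_calibration <- function(contents, intensities, q_ref = 1) {
  stopifnot(length(contents) == length(intensities), q_ref > 0)
  ok <- is.finite(contents) & is.finite(intensities)
  contents <- contents[ok]; intensities <- intensities[ok]
  if (any(contents <= 0)) stop("calibration contents must be positive")
  if (length(unique(contents)) < 3L) {
    stop("need at least 3 usable standards with distinct contents")
  }
  x <- log(contents / q_ref)
  fit <- stats::lm.fit(cbind(1, x), intensities)
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  if (!is.finite(b) || b <= 0) {
    stop("non-monotone calibration: fitted slope b = ", signif(b, 4),
         " (must be > 0)")
  }
  n <- length(contents)
  rsd <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else 0
  structure(
    list(a = a, b = b, q_ref = q_ref, residual_sd = rsd,
         domain = range(contents), n_standards = n),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: I = %.4g + %.4g * ln(q/%g); residual SD %.4g; domain [%.3g, %.3g] pg/ng (%d standards)\n",
    x$a, x$b, x$q_ref, x$residual_sd, x$domain[1], x$domain[2], x$n_standards))
  invisible(x)
}

#' Invert the standard curve (inverse prediction)
#'
#' `q = q_ref * exp((I - a)/b)`.  Intensities that map outside the content
#' domain spanned by the standards are flagged `extrapolated`, never
#' rejected.
#'
#' @param curve A [fit_calibration()] result.
#' @param intensity Background-corrected integral intensities.
#' @return `data.frame` with columns `intensity`, `content` (pg/ng DNA) and
#'   logical `extrapolated`.
#' @export
invert_calibration <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  content <- curve$q_ref * exp((intensity - curve$a) / curve$b)
  ## relative slack so contents at the domain edges are not flagged by
  ## floating-point jitter
  data.frame(
    intensity = intensity,
    content = content,
    extrapolated = content < curve$domain[1] * (1 - 1e-9) |
      content > curve$domain[2] * (1 + 1e-9)
  )
}

#' Aggregate replicate spot intensities into a sample content estimate
#'
#' Each replicate intensity is inverted through the standard curve; the
#' sample estimate is the arithmetic mean of the replicate contents, with
#' the per-spot coefficient of variation (`relative_sd`, the assay's
#' "relative standard error") and the standard error of the mean
#' (`content_se = SD/sqrt(n)`).
#'
#' @param intensities Background-corrected replicate intensities (>= 2
#'   unflagged values for an unflagged result).
#' @param curve A [fit_calibration()] result.
#' @param exclude Logical vector marking replicates to drop (e.g. saturated
#'   spots); default none.
#' @param sample_id Optional identifier carried into the result.
#' @return One-row `data.frame` of class `sample_quant`: `sample_id`,
#'   `content_mean`, `content_se`, `relative_sd`, `n_replicates`, flags
#'   `extrapolated` and `saturated_replicate`.
#' @examples
#' cal <- fit_calibration(c(1, exp(1), exp(2)), c(0, 10, 20))
#' quantify_sample(c(0, 10, 20), cal)
#' @export
quantify_sample <- function(intensities, curve, exclude = NULL,
                            sample_id = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  exclude <- exclude %||% rep(FALSE, length(intensities))
  stopifnot(length(exclude) == length(intensities))
  use <- intensities[!exclude]
  if (!length(use)) stop("all replicates flagged; nothing to quantify")
  inv <- invert_calibration(curve, use)
  n <- length(use)
  m <- mean(inv$content)
  s <- if (n > 1) stats::sd(inv$content) else 0
  data.frame(
    sample_id = sample_id,
    content_mean = m,
    content_se = s / sqrt(n),
    relative_sd = if (m > 0) s / m else 0,
    n_replicates = n,
    extrapolated = any(inv$extrapolated),
    saturated_replicate = any(exclude),
    stringsAsFactors = FALSE
  )
}

#' Quantify all samples on a measured membrane
#'
#' The full calibration stage: the background spot's corrected integral is
#' subtracted from every spot's corrected integral (floored at a small
#' positive epsilon), the standard curve is fitted on the unsaturated
#' calibration spots, and each sample's replicates are inverted and
#' aggregated with [quantify_sample()].
#'
#' @param measurements A `measurement_table` from [measure_membrane()].
#' @param eps Floor applied to net intensities after background-spot
#'   subtraction (default `1e-9`).
#' @param q_ref Reference content for the curve.
#' @return List of class `membrane_quant`: `curve` (the
#'   [fit_calibration()] result), `samples` (one [quantify_sample()] row per
#'   sample) and `spots` (per-replicate recovered contents).
#' @examples
#' lay <- spot_layout_grid(2)
#' mb <- make_membrane(lay, c(S1 = 10, S2 = 30), seed = 1)
#' mq <- quantify_membrane(measure_membrane(mb))
#' mq$samples
#' @export
quantify_membrane <- function(measurements, eps = 1e-9, q_ref = 1) {
  m <- as.data.frame(measurements)
  need <- c("spot_id", "role", "sample_id", "known_content", "integral",
            "saturated")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("measurement table missing: ",
                         paste(miss, collapse = ", "))
  bgr <- m$integral[m$role == "background"]
  if (!length(bgr)) stop("no background spot in measurement table")
  net <- pmax(m$integral - mean(bgr), eps)

  std <- m$role == "calibration" & !m$saturated
  curve <- fit_calibration(m$known_content[std], net[std], q_ref = q_ref)

  samp <- m$role == "sample_replicate"
  spots <- cbind(
    m[samp, c("spot_id", "sample_id", "saturated")],
    invert_calibration(curve, net[samp])
  )
  rownames(spots) <- NULL

  ids <- unique(m$sample_id[samp])
  samples <- do.call(rbind, lapply(ids, function(sid) {
    sel <- samp & m$sample_id == sid
    quantify_sample(net[sel], curve, exclude = m$saturated[sel],
                    sample_id = sid)
  }))
  structure(list(curve = curve, samples = samples, spots = spots),
            class = "membrane_quant")
}

#' @export
print.membrane_quant <- function(x, ...) {
  print(x$curve)
  cat(sprintf("%d samples quantified; mean per-spot CV %.3f\n",
              nrow(x$samples), mean(x$samples$relative_sd)))
  invisible(x)
}

#' Convert repeat content to copies per haploid genome
#'
#' A content of `q` pg repeat per ng genomic DNA is the mass fraction
#' `q/1000`; multiplying by the genome size and dividing by the repeat unit
#' length gives copies per genome:
#' `copies = (q/1000) * genome_size_bp / unit_length_bp`.
#'
#' @param content Content in pg/ng DNA (>= 0).
#' @param unit_length_bp Length of one repeat unit in bp (positive).
#' @param genome_size_bp Haploid genome size in bp (default 3.2e9 for
#'   human).
#' @return Copies per haploid genome.
#' @examples
#' content_to_copies(1.55, unit_length_bp = 13000)  # ~ 381 copies
#' @export
content_to_copies <- function(content, unit_length_bp,
                              genome_size_bp = 3.2e9) {
  if (unit_length_bp <= 0 || genome_size_bp <= 0) {
    stop("unit and genome lengths must be positive")
  }
  if (any(content < 0)) stop("content must be nonnegative")
  (content / 1000) * genome_size_bp / unit_length_bp
}
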