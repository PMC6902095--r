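#' Signal model for the dot-blot forward simulation
#'
#' The integral intensity of a spot carrying repeat content `q` (pg/ng DNA)
#' follows a logarithmic law with saturation,
#' \deqn{I(q) = \mathrm{clamp}(a + b \log(q/q_{ref}),\ 0,\ I_{sat}) + I_{bg},}
#' where `a` is the intensity at the reference content, `b` the intensity
#' gain per unit log-content, `I_sat` the saturation ceiling of the
#' colorimetric development, and `I_bg` the nonspecific signal that every
#' spot (including the non-homologous background spot) receives.
#'
#' @param intercept_a Intensity (arbitrary integral units) at `q = q_ref`.
#' @param slope_b Intensity per unit `ln(content)`; must be positive.
#' @param q_ref Reference content in pg/ng DNA (default 1).
#' @param saturation_level Maximum specific integral intensity.
#' @param background_level Baseline integral intensity of a spot with no
#'   homologous target (the background spot renders at exactly this level).
#' @return An object of class `signal_model`.
#' @seealso [noise_model()], [make_membrane()]
#' @examples
#' sm <- signal_model(intercept_a = 100, slope_b = 20)
#' forward_integral(sm, c(1, exp(1), exp(2)))
#' @export
signal_model <- function(intercept_a = 10000, slope_b = 2000, q_ref = 1,
                         saturation_level = 1e6, background_level = 500) {
  stopifnot(is.numeric(intercept_a), is.numeric(slope_b), is.numeric(q_ref))
  if (slope_b <= 0) stop("slope_b must be positive")
  if (q_ref <= 0) stop("q_ref must be positive")
  if (background_level < 0) stop("background_level must be nonnegative")
  if (saturation_level <= background_level) {
    stop("saturation_level must exceed background_level")
  }
  structure(
    list(intercept_a = intercept_a, slope_b = slope_b, q_ref = q_ref,
         saturation_level = saturation_level,
         background_level = background_level),
    class = "signal_model"
  )
}

#' Specific integral intensity for given contents under a signal model
#'
#' Applies the clamped logarithmic law and adds the background level; this is
#' the noiseless forward model the membrane generator renders.
#'
#' @param signal A [signal_model()].
#' @param q Contents in pg/ng DNA (positive).
#' @return Numeric vector of total integral intensities (specific + background).
#' @export
forward_integral <- function(signal, q) {
  stopifnot(inherits(signal, "signal_model"))
  if (any(q <= 0)) stop("contents must be positive")
  specific <- signal$intercept_a + signal$slope_b * log(q / signal$q_ref)
  pmin(pmax(specific, 0), signal$saturation_level) + signal$background_level
}

#' Noise model for the dot-blot forward simulation
#'
#' Two multiplicative stages act on the content scale before the signal
#' transform: a per-sample extraction stage (DNA isolation) and a per-spot
#' assay stage (spotting/hybridization/development).  Both are lognormal
#' with `sdlog = log(1 + cv)` so the requested coefficient of variation is
#' an exact parameter and contents stay positive.  Two further stages act on
#' the raster: additive Gaussian pixel noise and a smooth linear intensity
#' gradient across the membrane.
#'
#' The assay stage default of 5\% matches the relative standard error of the
#' hybridization step alone; combined with an extraction stage of about 10\%
#' it reproduces the typical 11\% total error of the full assay
#' (`sqrt(0.05^2 + 0.10^2) = 0.112`).
#'
#' @param assay_cv Relative SD of the per-spot multiplicative stage
#'   (default 0.05).
#' @param extraction_cv Relative SD of the per-sample multiplicative stage
#'   (default 0; set to about 0.10 to emulate the full wet-lab error chain).
#' @param pixel_sd Additive Gaussian pixel noise SD, raster units.
#' @param gradient_amplitude Peak-to-peak amplitude of a smooth linear
#'   background gradient across the raster diagonal.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(assay_cv = 0.05, extraction_cv = 0,
                        pixel_sd = 0, gradient_amplitude = 0) {
  vals <- c(assay_cv, extraction_cv, pixel_sd, gradient_amplitude)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all noise parameters must be finite and nonnegative")
  }
  structure(
    list(assay_cv = assay_cv, extraction_cv = extraction_cv,
         pixel_sd = pixel_sd, gradient_amplitude = gradient_amplitude),
    class = "noise_model"
  )
}

## lognormal sdlog corresponding to a target coefficient of variation
cv_to_sdlog <- function(cv) log(1 + cv)

#' @export
print.signal_model <- function(x, ...) {
  cat("Dot-blot signal model: I(q) = clamp(a + b*ln(q/q_ref), 0, sat) + bg\n")
  cat(sprintf("  a = %g, b = %g, q_ref = %g, sat = %g, bg = %g\n",
              x$intercept_a, x$slope_b, x$q_ref,
              x$saturation_level, x$background_level))
  invisible(x)
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "Dot-blot noise model: assay_cv = %g, extraction_cv = %g, pixel_sd = %g, gradient = %g\n",
    x$assay_cv, x$extraction_cv, x$pixel_sd, x$gradient_amplitude))
  invisible(x)
}
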