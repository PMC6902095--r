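#' Simulate a dot-blot membrane image
#'
#' Renders every spot in `layout` as an isotropic Gaussian profile truncated
#' at 3 standard deviations inside the spot's circular footprint
#' (`sigma = radius/3`), scaled so that the *discrete* pixel sum of the spot
#' equals the forward-model integral
#' `clamp(a + b*ln(q~/q_ref), 0, sat) + bg`, where `q~` is the true content
#' perturbed by the multiplicative noise stages.  Background spots render at
#' the background level alone.  Extraction noise is drawn once per sample;
#' assay noise once per spot (calibration standards receive assay noise but
#' not extraction noise, since they bypass the DNA-isolation step).
#'
#' @param layout A [spot_layout()]; needs at least 3 calibration spots with
#'   distinct positive contents, at least one background spot, and at least
#'   2 replicate spots per sample.
#' @param true_contents Named numeric vector of true contents (pg/ng DNA),
#'   names matching `layout$sample_id`; an unnamed vector is matched to
#'   samples in order of first appearance in the layout.
#' @param signal A [signal_model()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; the membrane is a pure function of
#'   `(layout, contents, signal, noise, seed)`.
#' @param dim Image dimensions `c(rows, cols)`; defaults to the layout's
#'   `image_dim` attribute.
#' @param bit_depth 8 or 16.
#' @param quantize If `TRUE` (default) pixel values are rounded to integers
#'   and clipped to `2^bit_depth - 1`, as in a real scan.  Set `FALSE` to
#'   keep the continuous raster (used for exact round-trip checks).
#' @return A list of class `membrane` with elements `image` (numeric matrix
#'   with attribute `bit_depth`), `layout`, and `truth` — a per-spot table of
#'   true content, perturbed content and the rendered target integral.
#' @examples
#' lay <- spot_layout_grid(2)
#' mb <- make_membrane(lay, c(S1 = 10, S2 = 30), seed = 1)
#' mb$truth[, c("spot_id", "true_content", "target_integral")]
#' @export
make_membrane <- function(layout, true_contents,
                          signal = signal_model(), noise = noise_model(),
                          seed = NULL, dim = NULL, bit_depth = 16L,
                          quantize = TRUE) {
  stopifnot(inherits(signal, "signal_model"), inherits(noise, "noise_model"))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  layout <- validate_membrane_layout(layout)
  dim <- dim %||% attr(layout, "image_dim")
  if (is.null(dim)) stop("image dimensions needed (layout lacks image_dim)")

  samples <- unique(layout$sample_id[layout$role == "sample_replicate"])
  if (is.null(names(true_contents))) {
    if (length(true_contents) != length(samples)) {
      stop("need one true content per sample")
    }
    names(true_contents) <- samples
  }
  if (!all(samples %in% names(true_contents))) {
    stop("true_contents missing samples: ",
         paste(setdiff(samples, names(true_contents)), collapse = ", "))
  }
  if (any(true_contents <= 0)) stop("true contents must be positive")

  bad <- layout$row - layout$radius < 1 | layout$row + layout$radius > dim[1] |
    layout$col - layout$radius < 1 | layout$col + layout$radius > dim[2]
  if (any(bad)) {
    stop("image too small for spots: ",
         paste(layout$spot_id[bad], collapse = ", "))
  }

  ## pairwise footprint overlap check
  n <- nrow(layout)
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(cbind(layout$row, layout$col)))
    lim <- outer(layout$radius, layout$radius, "+")
    diag(d2) <- Inf
    if (any(d2 < lim)) stop("overlapping spot footprints in layout")
  }

  with_seed(seed, {
    sd_ex <- cv_to_sdlog(noise$extraction_cv)
    sd_as <- cv_to_sdlog(noise$assay_cv)
    ex_factor <- stats::setNames(
      if (sd_ex > 0) exp(stats::rnorm(length(samples), 0, sd_ex))
      else rep(1, length(samples)),
      samples
    )

    truth <- layout
    truth$true_content <- NA_real_
    truth$perturbed_content <- NA_real_
    truth$target_integral <- NA_real_

    img <- matrix(0, nrow = dim[1], ncol = dim[2])
    if (noise$gradient_amplitude > 0) {
      rr <- (seq_len(dim[1]) - 1) / max(dim[1] - 1, 1)
      cc <- (seq_len(dim[2]) - 1) / max(dim[2] - 1, 1)
      img <- img + noise$gradient_amplitude * (outer(rr, cc, "+") / 2)
    }

    for (i in seq_len(n)) {
      role <- layout$role[i]
      if (role == "background") {
        target <- signal$background_level
      } else {
        q <- if (role == "calibration") layout$known_content[i]
             else true_contents[[layout$sample_id[i]]]
        qp <- q * (if (role == "sample_replicate")
                     ex_factor[[layout$sample_id[i]]] else 1)
        if (sd_as > 0) qp <- qp * exp(stats::rnorm(1, 0, sd_as))
        truth$true_content[i] <- q
        truth$perturbed_content[i] <- qp
        target <- forward_integral(signal, qp)
      }
      truth$target_integral[i] <- target
      img <- render_spot(img, layout$row[i], layout$col[i],
                         layout$radius[i], target)
    }

    if (noise$pixel_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise$pixel_sd),
                          nrow = dim[1])
    }
    img <- pmax(img, 0)
    if (quantize) img <- pmin(round(img), 2^bit_depth - 1)
    attr(img, "bit_depth") <- as.integer(bit_depth)

    structure(
      list(image = img, layout = layout,
           truth = as.data.frame(truth)[, c("spot_id", "role", "sample_id",
                                            "row", "col", "radius",
                                            "true_content",
                                            "perturbed_content",
                                            "target_integral")]),
      class = "membrane"
    )
  })
}

validate_membrane_layout <- function(layout) {
  stopifnot(inherits(layout, "data.frame"))
  cal <- layout[layout$role == "calibration", , drop = FALSE]
  if (nrow(cal) < 3L || length(unique(cal$known_content)) < 3L) {
    stop("layout needs >= 3 calibration spots with distinct contents")
  }
  if (any(cal$known_content <= 0)) stop("non-positive calibration content")
  if (!any(layout$role == "background")) {
    stop("layout needs at least one background spot")
  }
  reps <- table(layout$sample_id[layout$role == "sample_replicate"])
  if (length(reps) && any(reps < 2L)) {
    stop("each sample needs at least 2 replicate spots")
  }
  layout
}

## Add a truncated-Gaussian spot whose discrete pixel sum equals `target`.
## Pixel membership uses a centre-in-disk test; sigma = radius / 3 so the
## footprint edge sits at 3 sigma.
render_spot <- function(img, row0, col0, radius, target) {
  r1 <- max(1L, floor(row0 - radius)); r2 <- min(nrow(img), ceiling(row0 + radius))
  c1 <- max(1L, floor(col0 - radius)); c2 <- min(ncol(img), ceiling(col0 + radius))
  rr <- r1:r2; cc <- c1:c2
  d2 <- outer((rr - row0)^2, (cc - col0)^2, "+")
  mask <- d2 <= radius^2
  sigma <- radius / 3
  w <- exp(-d2 / (2 * sigma^2)) * mask
  s <- sum(w)
  if (s <= 0) stop("spot footprint contains no pixels")
  img[rr, cc] <- img[rr, cc] + target * w / s
  img
}

#' @export
print.membrane <- function(x, ...) {
  cat(sprintf("Simulated membrane: %d x %d px (%d-bit), %d spots (%s)\n",
              nrow(x$image), ncol(x$image), attr(x$image, "bit_depth"),
              nrow(x$layout),
              paste(names(table(x$layout$role)), table(x$layout$role),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Write / read the per-spot truth table of a simulated membrane
#'
#' @param truth The `truth` data frame from [make_membrane()].
#' @param path File path.
#' @return The path (write) or the table (read).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
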