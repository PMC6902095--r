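#' Integrate a single spot with local background correction
#'
#' Sums pixels whose centres fall inside the disk of the given radius and
#' subtracts `disk pixel count * median(annulus pixels)`, the robust local
#' background estimate.  The annulus defaults to radii
#' `(radius + 2, radius + 6)`.
#'
#' @param image Numeric matrix (raster), optionally with a `bit_depth`
#'   attribute used for the saturation test.
#' @param center Spot centre `c(row, col)` in pixels.
#' @param radius Disk radius in pixels.
#' @param annulus Inner and outer annulus radii; inner must be `>= radius`
#'   and the annulus must fit inside the image.
#' @return A one-row `data.frame`: `integral` (background-corrected integral
#'   intensity, may be negative), `local_background` (annulus median),
#'   `n_pixels`, and logical flags `saturated` (more than 1\% of disk pixels
#'   at the raster maximum) and `low_signal` (corrected integral below zero).
#' @examples
#' img <- matrix(10, 40, 40)
#' img[20, 20] <- 1010
#' integrate_spot(img, c(20, 20), radius = 5)
#' @export
integrate_spot <- function(image, center, radius,
                           annulus = radius + c(2, 6)) {
  stopifnot(length(center) == 2L, radius > 0, length(annulus) == 2L)
  if (annulus[1] < radius) stop("annulus inner radius must be >= spot radius")
  if (annulus[2] <= annulus[1]) stop("annulus outer must exceed inner")
  d <- dim(image)
  if (center[1] - annulus[2] < 1 || center[1] + annulus[2] > d[1] ||
      center[2] - annulus[2] < 1 || center[2] + annulus[2] > d[2]) {
    stop("annulus extends beyond the image")
  }
  r1 <- floor(center[1] - annulus[2]); r2 <- ceiling(center[1] + annulus[2])
  c1 <- floor(center[2] - annulus[2]); c2 <- ceiling(center[2] + annulus[2])
  rr <- r1:r2; cc <- c1:c2
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  patch <- image[rr, cc]
  disk <- d2 <= radius^2
  ann <- d2 > annulus[1]^2 & d2 <= annulus[2]^2
  if (!any(ann)) stop("empty annulus")
  n_disk <- sum(disk)
  local_bg <- stats::median(patch[ann])
  integral <- sum(patch[disk]) - n_disk * local_bg
  maxval <- 2^(attr(image, "bit_depth") %||% 16L) - 1
  data.frame(
    integral = integral,
    local_background = local_bg,
    n_pixels = n_disk,
    saturated = mean(patch[disk] >= maxval) > 0.01,
    low_signal = integral < 0
  )
}

#' Refine nominal spot centres by intensity-weighted centroid
#'
#' For each spot, pixels in a square window of half-width `search_window`
#' around the nominal centre are background-corrected by the window median
#' (negative residuals clipped to zero) and the centroid of the remaining
#' mass becomes the refined centre.  Spots whose corrected window total does
#' not exceed `low_signal_threshold` keep their nominal centre and are
#' flagged `low_signal`.
#'
#' @param image Numeric matrix.
#' @param layout A [spot_layout()]; nominal centres must lie inside the
#'   image and every window must fit within it.
#' @param search_window Window half-width in pixels (default 5, `>= 1`).
#' @param low_signal_threshold Minimum corrected window mass for refinement.
#' @return The layout with refined `row`/`col` and an added logical
#'   `low_signal` column.
#' @export
locate_spots <- function(image, layout, search_window = 5,
                         low_signal_threshold = 0) {
  stopifnot(search_window >= 1)
  d <- dim(image)
  out <- as.data.frame(layout)
  out$low_signal <- FALSE
  for (i in seq_len(nrow(out))) {
    r0 <- out$row[i]; c0 <- out$col[i]
    if (r0 < 1 || r0 > d[1] || c0 < 1 || c0 > d[2]) {
      stop("nominal centre of spot ", out$spot_id[i], " outside image")
    }
    rr <- round(r0 - search_window):round(r0 + search_window)
    cc <- round(c0 - search_window):round(c0 + search_window)
    if (min(rr) < 1 || max(rr) > d[1] || min(cc) < 1 || max(cc) > d[2]) {
      stop("search window of spot ", out$spot_id[i], " extends beyond image")
    }
    patch <- image[rr, cc]
    w <- pmax(patch - stats::median(patch), 0)
    tot <- sum(w)
    if (tot <= low_signal_threshold) {
      out$low_signal[i] <- TRUE
      next
    }
    out$row[i] <- sum(outer(rr, rep(1, length(cc))) * w) / tot
    out$col[i] <- sum(outer(rep(1, length(rr)), cc) * w) / tot
  }
  class(out) <- c("spot_layout", "data.frame")
  out
}

#' Measure every spot on a membrane
#'
#' Applies [locate_spots()] (optionally) and [integrate_spot()] to each spot
#' in the layout, producing one measurement row per spot with flags
#' propagated.  Background-role spots are measured identically to all
#' others.
#'
#' @param image Numeric matrix, or a `membrane` object.
#' @param layout A [spot_layout()]; defaults to the membrane's own layout.
#' @param refine If `TRUE`, refine centres with [locate_spots()] first.
#' @param search_window Passed to [locate_spots()].
#' @param annulus_offsets Inner/outer annulus offsets added to each spot
#'   radius (default `c(2, 6)`).
#' @return A `data.frame` of class `measurement_table`: layout columns plus
#'   `integral`, `local_background`, `saturated`, `low_signal`.
#' @examples
#' lay <- spot_layout_grid(2)
#' mb <- make_membrane(lay, c(S1 = 10, S2 = 30), seed = 1)
#' head(measure_membrane(mb))
#' @export
measure_membrane <- function(image, layout = NULL, refine = FALSE,
                             search_window = 5, annulus_offsets = c(2, 6)) {
  if (inherits(image, "membrane")) {
    layout <- layout %||% image$layout
    image <- image$image
  }
  if (is.null(layout)) stop("a spot layout is required")
  check_layout_on_image(layout, image, pad = annulus_offsets[2])
  lay <- as.data.frame(layout)
  lay$low_signal <- FALSE
  if (refine) lay <- as.data.frame(locate_spots(image, layout, search_window))
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    m <- integrate_spot(image, c(lay$row[i], lay$col[i]), lay$radius[i],
                        annulus = lay$radius[i] + annulus_offsets)
    m$low_signal <- m$low_signal | lay$low_signal[i]
    m
  })
  meas <- do.call(rbind, rows)
  out <- cbind(lay[, c("spot_id", "role", "sample_id", "row", "col",
                       "radius", "known_content")],
               meas[, c("integral", "local_background", "saturated",
                        "low_signal")])
  rownames(out) <- NULL
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' @rdname measure_membrane
#' @param x Measurement table.
#' @param path CSV path.
#' @export
write_measurements_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname measure_membrane
#' @export
read_measurements_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("measurement_table", "data.frame")
  out
}
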