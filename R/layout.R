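#' Spot layout tables
#'
#' A spot layout names every spot on a membrane: its role
#' (`"sample_replicate"`, `"calibration"` or `"background"`), the sample it
#' replicates, its nominal centre in pixel coordinates (1-based matrix
#' indices, row 1 at the top), its radius, and — for calibration standards —
#' the known repeat content in pg/ng DNA.
#'
#' @param spot_id Character vector of unique spot identifiers.
#' @param role One of `"sample_replicate"`, `"calibration"`, `"background"`
#'   per spot.
#' @param sample_id Sample identifier (`NA` for calibration/background spots).
#' @param row,col Nominal spot centres in pixels.
#' @param radius Spot radius in pixels (positive).
#' @param known_content Known content in pg/ng DNA for calibration spots,
#'   `NA` otherwise.
#' @return A `data.frame` of class `spot_layout`.
#' @seealso [spot_layout_grid()] for the standard grid arrangement.
#' @export
spot_layout <- function(spot_id, role, sample_id, row, col, radius,
                        known_content = NA_real_) {
  roles <- c("sample_replicate", "calibration", "background")
  if (!all(role %in% roles)) {
    stop("role must be one of: ", paste(roles, collapse = ", "))
  }
  if (anyDuplicated(spot_id)) stop("spot_id values must be unique")
  if (any(radius <= 0)) stop("spot radii must be positive")
  out <- data.frame(
    spot_id = as.character(spot_id),
    role = as.character(role),
    sample_id = as.character(sample_id),
    row = as.numeric(row),
    col = as.numeric(col),
    radius = as.numeric(radius),
    known_content = as.numeric(known_content),
    stringsAsFactors = FALSE
  )
  cal <- out$known_content[out$role == "calibration"]
  if (length(cal)) {
    if (any(is.na(cal)) || any(cal <= 0)) {
      stop("calibration spots need positive known_content")
    }
    if (length(unique(cal)) == 1L && length(cal) > 1L) {
      stop("calibration contents must not all be equal")
    }
  }
  class(out) <- c("spot_layout", "data.frame")
  out
}

#' Default calibration standard contents
#'
#' Six standards spaced log-uniformly over the working range of the assay
#' (6 to 44 pg/ng DNA, the span of repeat contents seen across cohorts).
#'
#' @param n Number of standards (default 6).
#' @param range Content range in pg/ng DNA to span log-uniformly.
#' @return Numeric vector of standard contents.
#' @export
default_standard_contents <- function(n = 6, range = c(6, 44)) {
  stopifnot(n >= 2, all(range > 0), range[2] > range[1])
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Standard grid layout for a simulated membrane
#'
#' Mirrors the usual filter arrangement: samples occupy a block of columns,
#' one column per sample with the replicate spots contiguous down the
#' column; below that block sits a marked row of calibration standards and
#' one background spot of DNA non-homologous to the probe.
#'
#' @param n_samples Number of DNA samples (each spotted `n_replicates` times).
#' @param standard_contents Known contents of the calibration standards.
#' @param radius Spot radius in pixels.
#' @param pitch Centre-to-centre spot spacing in pixels; must leave room for
#'   the background annulus used at measurement time (`radius + 6`).
#' @param margin Margin between outermost spot centres and the image edge.
#' @param n_replicates Replicates per sample (default 3, the standard
#'   triplicate).
#' @param sample_ids Optional sample identifiers (default `S1 ... Sn`).
#' @return A [spot_layout()] with an `image_dim` attribute giving the
#'   smallest raster (rows, cols) that accommodates all spots and annuli.
#' @examples
#' lay <- spot_layout_grid(n_samples = 4)
#' table(lay$role)
#' attr(lay, "image_dim")
#' @export
spot_layout_grid <- function(n_samples,
                             standard_contents = default_standard_contents(),
                             radius = 8, pitch = 26, margin = 20,
                             n_replicates = 3, sample_ids = NULL) {
  stopifnot(n_samples >= 1, n_replicates >= 2)
  if (pitch < 2 * radius + 2) stop("pitch too small for spot radius")
  if (margin < radius + 7) stop("margin must cover the measurement annulus")
  n_std <- length(standard_contents)
  sample_ids <- sample_ids %||% paste0("S", seq_len(n_samples))
  stopifnot(length(sample_ids) == n_samples)

  ncols <- max(n_samples, n_std + 1L)
  rows <- list(); cols <- list(); ids <- list(); roles <- list()
  sids <- list(); kq <- list()
  for (s in seq_len(n_samples)) {
    for (r in seq_len(n_replicates)) {
      ids[[length(ids) + 1L]] <- sprintf("%s_rep%d", sample_ids[s], r)
      roles[[length(roles) + 1L]] <- "sample_replicate"
      sids[[length(sids) + 1L]] <- sample_ids[s]
      rows[[length(rows) + 1L]] <- margin + (r - 1) * pitch
      cols[[length(cols) + 1L]] <- margin + (s - 1) * pitch
      kq[[length(kq) + 1L]] <- NA_real_
    }
  }
  std_row <- margin + (n_replicates + 0.5) * pitch
  for (k in seq_len(n_std)) {
    ids[[length(ids) + 1L]] <- sprintf("STD%d", k)
    roles[[length(roles) + 1L]] <- "calibration"
    sids[[length(sids) + 1L]] <- NA_character_
    rows[[length(rows) + 1L]] <- std_row
    cols[[length(cols) + 1L]] <- margin + (k - 1) * pitch
    kq[[length(kq) + 1L]] <- standard_contents[k]
  }
  ids[[length(ids) + 1L]] <- "BG"
  roles[[length(roles) + 1L]] <- "background"
  sids[[length(sids) + 1L]] <- NA_character_
  rows[[length(rows) + 1L]] <- std_row
  cols[[length(cols) + 1L]] <- margin + n_std * pitch
  kq[[length(kq) + 1L]] <- NA_real_

  lay <- spot_layout(
    spot_id = unlist(ids), role = unlist(roles), sample_id = unlist(sids),
    row = round(unlist(rows)), col = round(unlist(cols)),
    radius = radius, known_content = unlist(kq)
  )
  attr(lay, "image_dim") <- c(
    ceiling(max(lay$row) + margin),
    ceiling(max(lay$col) + margin)
  )
  lay
}

## shared layout validation against an image raster
check_layout_on_image <- function(layout, image, pad = 0) {
  stopifnot(inherits(layout, "data.frame"))
  d <- dim(image)
  bad <- layout$row - layout$radius - pad < 1 |
    layout$row + layout$radius + pad > d[1] |
    layout$col - layout$radius - pad < 1 |
    layout$col + layout$radius + pad > d[2]
  if (any(bad)) {
    stop("image too small: spots ", paste(layout$spot_id[bad], collapse = ", "),
         " (with padding ", pad, " px) fall outside the raster")
  }
  invisible(TRUE)
}

#' Read / write a spot layout as CSV
#'
#' Column order and names are fixed: `spot_id, role, sample_id, row, col,
#' radius, known_content`.
#'
#' @param layout A [spot_layout()].
#' @param path File path.
#' @return `read_layout_csv()` returns a [spot_layout()];
#'   `write_layout_csv()` returns `path` invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "role", "sample_id", "row", "col", "radius",
            "known_content")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("layout CSV missing columns: ",
                         paste(miss, collapse = ", "))
  spot_layout(df$spot_id, df$role, df$sample_id, df$row, df$col, df$radius,
              df$known_content)
}
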