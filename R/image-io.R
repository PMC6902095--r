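#' Write a membrane image to disk
#'
#' The native format is plain-text PGM (`P2`), which round-trips 8- and
#' 16-bit grayscale rasters without any external library.  PNG output (also
#' 16-bit grayscale) is available when the `png` package is installed.
#' Format is chosen from the file extension (`.pgm` or `.png`).
#'
#' @param image Numeric matrix with a `bit_depth` attribute (8 or 16), or
#'   a `membrane` object from [make_membrane()].
#' @param path Output path ending in `.pgm` or `.png`.
#' @return `path`, invisibly.
#' @seealso [read_membrane_image()]
#' @export
write_membrane_image <- function(image, path) {
  if (inherits(image, "membrane")) image <- image$image
  bit <- attr(image, "bit_depth") %||% 16L
  maxval <- 2^bit - 1
  img <- pmin(pmax(round(image), 0), maxval)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    write_pgm(img, path, maxval = maxval)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG output needs the 'png' package; use .pgm instead")
    }
    png::writePNG(img / maxval, path)
  } else {
    stop("unsupported image extension: ", ext, " (use .pgm or .png)")
  }
  invisible(path)
}

#' Read a membrane image from disk
#'
#' @param path Path to a `.pgm` (P2/P5) or `.png` grayscale image.
#' @return Numeric matrix with attribute `bit_depth`.
#' @export
read_membrane_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("PNG input needs the 'png' package")
    }
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    img <- round(arr * 65535)
    attr(img, "bit_depth") <- 16L
    return(img)
  }
  stop("unsupported image extension: ", ext)
}

## Plain-text PGM (P2) writer; values already integer in [0, maxval].
write_pgm <- function(img, path, maxval = 65535) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  ## one image row per line, row-major from the top
  apply(img, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

## PGM reader for ASCII P2 and binary P5.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  wd <- as.integer(tokens[1]); ht <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  npix <- wd * ht
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = npix, quiet = TRUE)
  } else {
    if (maxval > 255) {
      readBin(con, "integer", n = npix, size = 2L, signed = FALSE,
              endian = "big")
    } else {
      as.integer(readBin(con, "raw", n = npix))
    }
  }
  img <- matrix(vals, nrow = ht, ncol = wd, byrow = TRUE)
  attr(img, "bit_depth") <- if (maxval > 255) 16L else 8L
  img
}
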