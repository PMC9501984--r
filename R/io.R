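# Reading and writing 8-bit raster images (PNG/TIFF) and pixel orderings.

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '%s' (use .png, .tif or .tiff)", ext))
}

# PNG stores bit depth and color type at fixed offsets in the IHDR chunk
# (bytes 25 and 26 of the file); png::readPNG rescales silently, so the
# header is inspected first to reject >8-bit and palette files outright.
png_header_info <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("truncated PNG file: ", path)
  list(bit_depth = as.integer(hdr[25L]), color_type = as.integer(hdr[26L]))
}

#' Read an 8-bit grayscale or RGB image
#'
#' Reads a PNG or TIFF file into an integer matrix (grayscale) or
#' `m x n x 3` integer array (RGB) with values in `0:255`.  Images with a
#' bit depth above 8 and palette-indexed PNGs are rejected: the ordering and
#' specification algorithms are stated for 8-bit levels and silent rescaling
#' would change the histogram.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param alpha `"error"` (default) to reject images with an alpha channel,
#'   `"strip"` to drop it.
#' @return an integer matrix or `m x n x 3` integer array in `0:255`.
#' @seealso [write_image()]
#' @export
read_image <- function(path, alpha = c("error", "strip")) {
  alpha <- match.arg(alpha)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- image_format(path)
  if (fmt == "png") {
    info <- png_header_info(path)
    if (info$bit_depth > 8L) {
      stop(sprintf("unsupported bit depth %d (only 8-bit images are supported)",
                   info$bit_depth))
    }
    if (info$color_type == 3L) {
      stop("palette-indexed PNG images are not supported")
    }
    x <- png::readPNG(path)
    x <- round(x * 255)
  } else {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8L)) {
      stop(sprintf("unsupported bit depth %d (only 8-bit images are supported)",
                   max(bits)))
    }
    x <- round(x * 255)
  }
  nd <- length(dim(x))
  if (nd == 3L) {
    ch <- dim(x)[3L]
    if (ch %in% c(2L, 4L)) {
      if (alpha == "error") {
        stop("image has an alpha channel; pass alpha = \"strip\" to drop it")
      }
      x <- if (ch == 2L) x[, , 1L] else x[, , 1:3]
    } else if (ch == 1L) {
      x <- x[, , 1L]
    } else if (ch != 3L) {
      stop(sprintf("unsupported channel count: %d", ch))
    }
  }
  x <- if (length(dim(x)) == 3L) array(as.integer(x), dim = dim(x))
       else matrix(as.integer(x), nrow(x), ncol(x))
  assert_image(x)
}

#' Write an 8-bit image losslessly
#'
#' Writes an integer image with values in `0:255` to PNG or TIFF so that
#' [read_image()] recovers it bit-exactly.  Non-integer or out-of-range
#' values are an error -- they are never clipped or rounded silently.
#'
#' @param img integer matrix or `m x n x 3` array in `0:255`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_image <- function(img, path) {
  img <- assert_image(img)
  fmt <- image_format(path)
  x <- img / 255
  if (fmt == "png") {
    png::writePNG(x, target = path)
  } else {
    tiff::writeTIFF(x, where = path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Export a pixel ordering as text
#'
#' One 1-based column-major linear index per line, in rank order (rank 1
#' first).
#'
#' @param ordering integer permutation as returned by [order_pixels()] or
#'   [order_elements_color()].
#' @param path output file.
#' @export
write_ordering <- function(ordering, path) {
  writeLines(format(as.integer(ordering), scientific = FALSE, trim = TRUE),
             con = path)
  invisible(path)
}
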