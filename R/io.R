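#' Read an RGB image from PNG or JPEG
#'
#' Returns an `H x W x 3` numeric array with values in 0-255. Grayscale files
#' are replicated across channels; an alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @return an RGB image array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else {
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  }
  round(raw * 255)
}

#' Write an RGB image to PNG
#'
#' @param image an `H x W x 3` array, values 0-255.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path PNG path.
#' @return integer matrix with values in \{0, 1\}.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  as_binary_mask((raw > 0.5) * 1L)
}

#' Write a binary mask as an 8-bit PNG with values \{0, 255\}
#'
#' @param mask integer matrix in \{0, 1\}.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
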