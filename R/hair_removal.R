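#' Convert an RGB image to grayscale (ITU-R BT.601 luminance)
#'
#' Per-pixel `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer and
#' clamped to 0-255.
#'
#' @param image an `H x W x 3` array with values in 0-255.
#' @return numeric matrix in 0-255.
#' @export
to_grayscale <- function(image) {
  assert_rgb_image(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  dim(g) <- dim(image)[1:2]  # single-row/column images drop dims above
  clamp(round(g), 0, 255)
}

#' Cross-shaped structuring element
#'
#' An odd-sized square footprint whose middle row and middle column are
#' foreground: the element used for hair detection is the 17x17 cross.
#'
#' @param size odd positive integer (default 17).
#' @return an object of class `structuring_element` with fields `footprint`
#'   (0/1 integer matrix), `shape_tag` and `size`.
#' @export
cross_element <- function(size = 17L) {
  if (length(size) != 1L || size < 1 || size %% 2 == 0) {
    stop("size must be an odd positive integer", call. = FALSE)
  }
  size <- as.integer(size)
  fp <- matrix(0L, size, size)
  mid <- (size + 1L) %/% 2L
  fp[mid, ] <- 1L
  fp[, mid] <- 1L
  structure(list(footprint = fp, shape_tag = "cross", size = size),
            class = "structuring_element")
}

se_footprint <- function(se) {
  if (inherits(se, "structuring_element")) return(se$footprint)
  if (is.matrix(se)) {
    storage.mode(se) <- "integer"
    return(se)
  }
  stop("expected a structuring_element or a 0/1 matrix", call. = FALSE)
}

#' Grayscale dilation, erosion and closing
#'
#' Sliding-window maximum (dilation) / minimum (erosion) over the footprint;
#' closing is dilation followed by erosion with the same footprint. Out-of-image
#' samples replicate the nearest edge pixel, so closing is extensive
#' (`close(A) >= A`) everywhere including borders.
#'
#' @param image numeric matrix (grayscale).
#' @param se a [cross_element()] or 0/1 footprint matrix.
#' @return numeric matrix of the same size.
#' @export
gray_dilate <- function(image, se) {
  cpp_gray_dilate(image, se_footprint(se))
}

#' @rdname gray_dilate
#' @export
gray_erode <- function(image, se) {
  cpp_gray_erode(image, se_footprint(se))
}

#' @rdname gray_dilate
#' @export
gray_close <- function(image, se) {
  fp <- se_footprint(se)
  cpp_gray_erode(cpp_gray_dilate(image, fp), fp)
}

#' Black top-hat filter
#'
#' Closing of the image minus the image itself; non-negative everywhere, it
#' highlights dark structures thinner than the structuring element, such as
#' hair shafts.
#'
#' @inheritParams gray_dilate
#' @return non-negative numeric matrix.
#' @export
black_tophat <- function(image, se) {
  gray_close(image, se) - image
}

#' Hair mask from a top-hat response
#'
#' Foreground wherever the top-hat value strictly exceeds `threshold`
#' (default 10 on the 0-255 scale).
#'
#' @param tophat matrix from [black_tophat()].
#' @param threshold non-negative scalar.
#' @return integer matrix in \{0, 1\}.
#' @export
hair_mask <- function(tophat, threshold = 10) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  as_binary_mask((tophat > threshold) * 1L)
}

#' Inpainting configuration
#'
#' @param radius neighborhood radius (pixels) for the weighted average used by
#'   fast-marching inpainting.
#' @param threshold hair-mask threshold applied to the black top-hat response.
#' @return an object of class `inpaint_config`.
#' @export
inpaint_config <- function(radius = 5L, threshold = 10) {
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  structure(list(radius = as.integer(radius), threshold = as.numeric(threshold)),
            class = "inpaint_config")
}

#' Fast-marching inpainting
#'
#' Fills masked pixels in order of increasing distance from the mask boundary
#' (fast marching method). Each filled value is a normalized weighted average
#' of already-known pixels within `cfg$radius`, weighted by the product of a
#' direction factor (alignment with the distance gradient), an inverse-square
#' distance factor and a level-set proximity factor. Pixels outside the mask
#' are returned bit-identical; a masked pixel with no known pixel in reach has
#' its neighborhood widened until one is found.
#'
#' @param image RGB image array (0-255).
#' @param mask binary matrix of pixels to fill, same height/width as `image`.
#' @param cfg an [inpaint_config()].
#' @return inpainted RGB image, integer-valued in 0-255.
#' @export
inpaint_fmm <- function(image, mask, cfg = inpaint_config()) {
  assert_rgb_image(image)
  assert_mask(mask)
  if (!all(dim(mask) == dim(image)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (all(mask == 1L)) {
    stop("mask covers the whole image: nothing to inpaint from", call. = FALSE)
  }
  out <- cpp_inpaint_telea(image, mask, cfg$radius)
  filled <- round(out)
  dim(filled) <- dim(image)
  if (is.integer(image)) storage.mode(filled) <- "integer"
  filled
}

#' Remove hair artifacts from a dermoscopic image
#'
#' The four-stage hair-removal algorithm: grayscale conversion, black top-hat
#' with a `se_size` x `se_size` cross structuring element, thresholding of the
#' top-hat response into a hair mask, and fast-marching inpainting of the
#' masked pixels in the RGB image. Works at the image's native resolution;
#' resize afterwards if a fixed network input size is needed.
#'
#' @param image RGB image array (0-255).
#' @param cfg an [inpaint_config()] carrying the mask threshold and the
#'   inpainting radius.
#' @param se_size odd size of the cross structuring element (default 17).
#' @param return_mask also return the detected hair mask.
#' @return the inpainted RGB image, or (with `return_mask = TRUE`) a list with
#'   `image` and `hair_mask`.
#' @export
remove_hair <- function(image, cfg = inpaint_config(), se_size = 17L,
                        return_mask = FALSE) {
  assert_rgb_image(image)
  gray <- to_grayscale(image)
  se <- cross_element(se_size)
  th <- black_tophat(gray, se)
  msk <- hair_mask(th, cfg$threshold)
  out <- if (any(msk == 1L)) inpaint_fmm(image, msk, cfg) else image
  if (return_mask) list(image = out, hair_mask = msk) else out
}
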