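#' Resize an image (and optionally its mask) to network resolution
#'
#' Images are resampled with bilinear interpolation (half-pixel centers) and
#' rounded back to integers; masks use nearest-neighbor so they stay strictly
#' binary. At the target size both are returned unchanged.
#'
#' @param image RGB image array (0-255).
#' @param mask optional binary matrix of the same height/width.
#' @param size target side length (default 256, the network input size).
#' @return list with `image` and `mask` (`NULL` if no mask was given).
#' @export
resize_pair <- function(image, mask = NULL, size = 256L) {
  assert_rgb_image(image)
  if (!is.null(mask)) {
    assert_mask(mask)
    if (!all(dim(mask) == dim(image)[1:2])) {
      stop("mask and image dimensions differ", call. = FALSE)
    }
  }
  size <- as.integer(size)
  img <- if (all(dim(image)[1:2] == size)) {
    image
  } else {
    round(clamp(cpp_resize_bilinear(image, size, size), 0, 255))
  }
  msk <- if (is.null(mask)) {
    NULL
  } else if (all(dim(mask) == size)) {
    mask
  } else {
    as_binary_mask(cpp_resize_nearest(mask, size, size))
  }
  list(image = img, mask = msk)
}

#' Standardize an image to zero mean and unit variance
#'
#' Subtracts the image mean and divides by the image standard deviation,
#' computed jointly over all pixels and channels (population denominator, so a
#' balanced two-valued image maps exactly to +/-1). A constant image maps to
#' all zeros and records `source_sd = 0`.
#'
#' @param image RGB image array.
#' @return object of class `normalized_image`: list with `pixels` (array of
#'   the same shape), `source_mean`, `source_sd`.
#' @export
normalize <- function(image) {
  assert_rgb_image(image)
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  px <- if (s == 0) array(0, dim = dim(image)) else (image - m) / s
  structure(list(pixels = px, source_mean = m, source_sd = s),
            class = "normalized_image")
}
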