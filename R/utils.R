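# internal helpers shared across modules

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  }
  if (dim(image)[3] != 3L) {
    stop(sprintf("`%s` must have exactly 3 channels, got %d", arg,
                 dim(image)[3]), call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  if (!all(mask %in% c(0L, 1L))) {
    stop(sprintf("`%s` must only contain 0/1 values", arg), call. = FALSE)
  }
  invisible(mask)
}

as_binary_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}
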