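#' Configuration for the synthetic dermoscopy generator
#'
#' The generator emulates the features of dermoscopic images that the
#' segmentation pipeline has to cope with: a skin-toned background with
#' Gaussian pixel noise, one connected darker lesion whose boundary is a
#' radially perturbed ellipse, and optional thin dark hair strokes drawn as
#' hard (non anti-aliased) curves so their pixel mask is exact.
#'
#' @param image_size side of the square image in pixels.
#' @param lesion_area_fraction_range ordered pair strictly inside (0,1); the
#'   foreground fraction of every generated mask falls in this interval.
#' @param lesion_darkening intensity offset (0-255 scale) subtracted from the
#'   skin color inside the lesion.
#' @param border_irregularity amplitude of the radial boundary perturbation,
#'   in (0, 1); 0 gives an exact ellipse.
#' @param n_hairs number of hair strokes added by [add_hair_artifacts()].
#' @param hair_width_range pair of positive integers, stroke width in pixels.
#' @param hair_intensity gray value of hair strokes (dark, 0-255).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_size = 256,
                         lesion_area_fraction_range = c(0.05, 0.40),
                         lesion_darkening = 95,
                         border_irregularity = 0.15,
                         n_hairs = 6,
                         hair_width_range = c(1L, 3L),
                         hair_intensity = 40,
                         noise_sd = 3,
                         seed = 1L) {
  if (length(image_size) != 1L || !is.finite(image_size) || image_size < 1) {
    stop("image_size must be a positive integer", call. = FALSE)
  }
  fr <- lesion_area_fraction_range
  if (length(fr) != 2L || fr[1] >= fr[2] || fr[1] <= 0 || fr[2] >= 1) {
    stop("lesion_area_fraction_range must be ordered and strictly inside (0,1)",
         call. = FALSE)
  }
  if (border_irregularity < 0 || border_irregularity >= 1) {
    stop("border_irregularity must lie in [0, 1)", call. = FALSE)
  }
  if (n_hairs < 0) stop("n_hairs must be non-negative", call. = FALSE)
  hw <- hair_width_range
  if (length(hw) != 2L || any(hw < 1) || hw[1] > hw[2]) {
    stop("hair_width_range must be an ordered pair of positive integers",
         call. = FALSE)
  }
  if (hair_intensity < 0 || hair_intensity > 255) {
    stop("hair_intensity must be in 0-255", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    lesion_area_fraction_range = as.numeric(fr),
    lesion_darkening = as.numeric(lesion_darkening),
    border_irregularity = as.numeric(border_irregularity),
    n_hairs = as.integer(n_hairs),
    hair_width_range = as.integer(hw),
    hair_intensity = as.numeric(hair_intensity),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "synth_config")
}

# fixed base colors (R, G, B): reproducibility is preferred over realism
.skin_color <- c(205, 160, 144)

#' Generate one synthetic dermoscopy image with its lesion mask
#'
#' The lesion boundary is r(theta) = r0(theta) * (1 + a * n(theta)) where
#' r0 is an ellipse radius, a is `border_irregularity` and n is a smooth
#' band-limited noise function normalized to |n| <= 1. The base ellipse area
#' is sampled so that the discrete foreground fraction is guaranteed to stay
#' inside `lesion_area_fraction_range` for any realization of n (worst-case
#' factor (1 +/- a)^2, plus a 5% margin for pixel discretization).
#'
#' @param config a [synth_config()].
#' @return list with `image` (H x W x 3 array, 0-255), `mask` (integer matrix
#'   in \{0,1\}; its foreground is exactly the set of lesion-colored pixels
#'   before noise) and `geometry` (the sampled ellipse center, semi-axes and
#'   orientation, useful as ground truth in tests).
#' @export
generate_lesion_image <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    S <- config$image_size
    a <- config$border_irregularity
    fr <- config$lesion_area_fraction_range
    fb_lo <- fr[1] / (1 - a)^2 * 1.05
    fb_hi <- fr[2] / (1 + a)^2 * 0.95
    if (fb_lo >= fb_hi) {
      stop("lesion_area_fraction_range too narrow for this border_irregularity",
           call. = FALSE)
    }
    rho <- runif(1, 0.55, 0.95)         # axis ratio b/a
    fb <- runif(1, fb_lo, fb_hi)        # base ellipse area fraction
    # largest semi-major axis that keeps the perturbed boundary inside the image
    a_fit <- (S / 2 - 3) / (1 + a)
    fb <- min(fb, pi * rho * a_fit^2 / S^2)
    aax <- sqrt(fb * S^2 / (pi * rho))
    bax <- rho * aax
    phi <- runif(1, 0, pi)
    margin <- aax * (1 + a) + 2
    cx <- clamp(S / 2 + runif(1, -0.05, 0.05) * S, margin, S + 1 - margin)
    cy <- clamp(S / 2 + runif(1, -0.05, 0.05) * S, margin, S + 1 - margin)

    if (a > 0) {
      ks <- 2:5                          # low-order harmonics only
      ck <- rnorm(length(ks))
      sk <- rnorm(length(ks))
      nf_raw <- function(th) {
        v <- numeric(length(th))
        for (i in seq_along(ks)) {
          v <- v + ck[i] * cos(ks[i] * th) + sk[i] * sin(ks[i] * th)
        }
        v
      }
      nmax <- max(abs(nf_raw(seq(0, 2 * pi, length.out = 4096))))
      nf <- function(th) nf_raw(th) / nmax
    } else {
      nf <- function(th) numeric(length(th))
    }

    xs <- matrix(rep(seq_len(S), each = S), S, S) - cx   # column coordinate
    ys <- matrix(rep(seq_len(S), times = S), S, S) - cy  # row coordinate
    u <- cos(phi) * xs + sin(phi) * ys
    v <- -sin(phi) * xs + cos(phi) * ys
    rr <- sqrt((u / aax)^2 + (v / bax)^2)
    theta <- atan2(v, u)
    mask <- as_binary_mask((rr <= 1 + a * nf(theta)) * 1L)

    lesion <- clamp(.skin_color - config$lesion_darkening, 0, 255)
    image <- array(0, dim = c(S, S, 3L))
    for (c in 1:3) {
      ch <- matrix(.skin_color[c], S, S)
      ch[mask == 1L] <- lesion[c]
      if (config$noise_sd > 0) {
        ch <- ch + matrix(rnorm(S * S, 0, config$noise_sd), S, S)
      }
      image[, , c] <- round(clamp(ch, 0, 255))
    }
    list(image = image, mask = mask,
         geometry = list(cx = cx, cy = cy, a = aax, b = bax, phi = phi,
                         irregularity = a))
  })
}

#' Overlay synthetic hair strokes on an image
#'
#' Draws `n_hairs` smooth dark curves (quadratic Bezier arcs spanning the
#' image) of widths sampled from `hair_width_range`, stamped as hard strokes
#' with constant intensity `hair_intensity` in all channels. The returned
#' mask records exactly the stamped pixels; everything outside it is
#' untouched.
#'
#' @param image an RGB image array.
#' @param config a [synth_config()]; `n_hairs = 0` returns the input
#'   unchanged with an empty mask.
#' @return list with `image` and the binary `hair_mask` of altered pixels.
#' @export
add_hair_artifacts <- function(image, config) {
  assert_rgb_image(image)
  stopifnot(inherits(config, "synth_config"))
  H <- dim(image)[1]; W <- dim(image)[2]
  mask <- matrix(0L, H, W)
  if (config$n_hairs == 0L) {
    return(list(image = image, hair_mask = as_binary_mask(mask)))
  }
  local_seed(config$seed + 1299721L, {
    out <- image
    span_min <- 0.45 * min(H, W)
    for (h in seq_len(config$n_hairs)) {
      repeat {
        p0 <- c(runif(1, 1, H), runif(1, 1, W))
        p1 <- c(runif(1, 1, H), runif(1, 1, W))
        len <- sqrt(sum((p1 - p0)^2))
        if (len >= span_min) break
      }
      d <- p1 - p0
      perp <- c(-d[2], d[1]) / len
      ctrl <- (p0 + p1) / 2 + perp * runif(1, -0.25, 0.25) * len
      width <- if (config$hair_width_range[1] == config$hair_width_range[2]) {
        config$hair_width_range[1]
      } else {
        sample(config$hair_width_range[1]:config$hair_width_range[2], 1L)
      }
      ts <- seq(0, 1, length.out = max(64L, 4L * ceiling(len)))
      py <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * ctrl[1] + ts^2 * p1[1]
      px <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * ctrl[2] + ts^2 * p1[2]
      r <- width / 2
      ri <- ceiling(r)
      for (k in seq_along(ts)) {
        if (width == 1L) {
          i <- round(py[k]); j <- round(px[k])
          if (i >= 1 && i <= H && j >= 1 && j <= W) mask[i, j] <- 1L
        } else {
          i0 <- max(1, floor(py[k] - ri)); i1 <- min(H, ceiling(py[k] + ri))
          j0 <- max(1, floor(px[k] - ri)); j1 <- min(W, ceiling(px[k] + ri))
          if (i0 > i1 || j0 > j1) next
          for (j in j0:j1) {
            dy <- (i0:i1) - py[k]
            dx <- j - px[k]
            hit <- which(dy * dy + dx * dx <= r * r)
            if (length(hit)) mask[i0 - 1 + hit, j] <- 1L
          }
        }
      }
    }
    idx <- mask == 1L
    for (c in 1:3) {
      ch <- out[, , c]
      ch[idx] <- config$hair_intensity
      out[, , c] <- ch
    }
    list(image = out, hair_mask = as_binary_mask(mask))
  })
}

#' Generate a synthetic dataset, optionally writing it to disk
#'
#' Image i uses seed `config$seed + i - 1`, so datasets are reproducible and
#' extendable. When `dir` is given, writes `img_%04d.png`, `mask_%04d.png`
#' and a `manifest.csv` listing the pairs.
#'
#' @param n number of images.
#' @param config a [synth_config()]; its `n_hairs` field sets whether hair is
#'   overlaid (masks always mark the lesion, not the hair).
#' @param dir optional output directory.
#' @param with_hair overlay hair strokes (default: `config$n_hairs > 0`).
#' @return invisibly, a list of `list(image, mask)` pairs.
#' @export
synth_dataset <- function(n, config = synth_config(), dir = NULL,
                          with_hair = config$n_hairs > 0L) {
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    gen <- generate_lesion_image(cfg_i)
    if (with_hair && config$n_hairs > 0L) {
      gen$image <- add_hair_artifacts(gen$image, cfg_i)$image
    }
    pairs[[i]] <- list(image = gen$image, mask = gen$mask)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- data.frame(image = character(n), mask = character(n))
    for (i in seq_len(n)) {
      fi <- sprintf("img_%04d.png", i)
      fm <- sprintf("mask_%04d.png", i)
      write_image(pairs[[i]]$image, file.path(dir, fi))
      write_mask(pairs[[i]]$mask, file.path(dir, fm))
      rows$image[i] <- fi
      rows$mask[i] <- fm
    }
    write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(pairs)
}

#' Load an image/mask dataset written by [synth_dataset()] or the CLI
#'
#' @param dir directory containing `manifest.csv`.
#' @return list of `list(image, mask)` pairs (mask `NULL` when absent).
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  rows <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(rows)), function(i) {
    msk <- if (!is.na(rows$mask[i]) && nzchar(rows$mask[i])) {
      read_mask(file.path(dir, rows$mask[i]))
    }
    list(image = read_image(file.path(dir, rows$image[i])), mask = msk)
  })
}
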