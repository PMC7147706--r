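test_that("config validation rejects impossible settings", {
  expect_error(synth_config(image_size = 0), "positive")
  expect_error(synth_config(lesion_area_fraction_range = c(0.4, 0.05)),
               "ordered")
  expect_error(synth_config(lesion_area_fraction_range = c(0, 0.4)), "ordered")
  expect_error(synth_config(border_irregularity = 1.2), "irregularity")
  expect_error(synth_config(n_hairs = -1), "non-negative")
  expect_error(synth_config(hair_width_range = c(3, 1)), "ordered")
})

test_that("zero irregularity and zero noise give an exact filled ellipse", {
  cfg <- synth_config(image_size = 128, border_irregularity = 0, noise_sd = 0,
                      seed = 3)
  g <- generate_lesion_image(cfg)
  geo <- g$geometry
  # recompute the ellipse inequality independently from the reported geometry
  xs <- matrix(rep(1:128, each = 128), 128, 128) - geo$cx
  ys <- matrix(rep(1:128, times = 128), 128, 128) - geo$cy
  u <- cos(geo$phi) * xs + sin(geo$phi) * ys
  v <- -sin(geo$phi) * xs + cos(geo$phi) * ys
  inside <- (u / geo$a)^2 + (v / geo$b)^2 <= 1
  expect_identical(g$mask == 1L, inside)
  # and the mask is exactly the set of lesion-colored pixels
  lesion_px <- g$image[, , 1] < 205
  expect_identical(g$mask == 1L, lesion_px)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(image_size = 96, seed = 11)
  a <- generate_lesion_image(cfg)
  b <- generate_lesion_image(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # a different seed gives a different lesion
  cfg2 <- synth_config(image_size = 96, seed = 12)
  expect_false(identical(generate_lesion_image(cfg2)$mask, a$mask))
})

test_that("mask foreground fractions always fall in the configured range", {
  fractions <- vapply(seq_len(1000), function(i) {
    cfg <- synth_config(image_size = 128, seed = i)
    mean(generate_lesion_image(cfg)$mask)
  }, numeric(1))
  expect_true(all(fractions >= 0.05))
  expect_true(all(fractions <= 0.40))
  # the range is actually exercised, not collapsed to a point
  expect_gt(diff(range(fractions)), 0.1)
})

test_that("lesion is a single connected component", {
  for (seed in c(2, 9, 33)) {
    cfg <- synth_config(image_size = 128, seed = seed)
    m <- generate_lesion_image(cfg)$mask
    # flood fill from one foreground pixel must reach all of them
    start <- which(m == 1L, arr.ind = TRUE)[1, ]
    seen <- matrix(FALSE, nrow(m), ncol(m))
    stack <- list(start)
    seen[start[1], start[2]] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] == 1L && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    expect_identical(sum(seen), sum(m == 1L))
  }
})

test_that("hair overlay honors the identity, determinism and mask contracts", {
  cfg <- synth_config(image_size = 128, seed = 5, n_hairs = 0)
  img <- generate_lesion_image(cfg)$image
  h0 <- add_hair_artifacts(img, cfg)
  expect_identical(h0$image, img)
  expect_identical(sum(h0$hair_mask), 0L)

  cfg5 <- synth_config(image_size = 128, seed = 5, n_hairs = 5)
  h1 <- add_hair_artifacts(img, cfg5)
  h2 <- add_hair_artifacts(img, cfg5)
  expect_identical(h1$image, h2$image)
  expect_identical(h1$hair_mask, h2$hair_mask)

  changed <- apply(h1$image != img, c(1, 2), any)
  expect_true(all(h1$hair_mask[changed] == 1L))  # changed pixels within mask
  expect_gt(sum(h1$hair_mask), 0L)
  # hair pixels carry the configured intensity in every channel
  for (c in 1:3) {
    expect_true(all(h1$image[, , c][h1$hair_mask == 1L] == cfg5$hair_intensity))
  }
})

test_that("dataset writer round-trips through PNG and manifest", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(image_size = 64, seed = 21, n_hairs = 2)
  pairs <- synth_dataset(3, cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_dataset(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$image, pairs[[i]]$image)
    expect_identical(back[[i]]$mask, pairs[[i]]$mask)
  }
})
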