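test_that("grayscale conversion uses BT.601 luminance, rounded and clamped", {
  black <- array(0, c(4, 4, 3))
  expect_true(all(to_grayscale(black) == 0))
  white <- array(255, c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  px <- array(0, c(1, 1, 3))
  px[1, 1, ] <- c(100, 150, 200)
  expect_equal(to_grayscale(px)[1, 1], 141)  # round(29.9 + 88.05 + 22.8)
  expect_error(to_grayscale(array(0, c(4, 4, 2))), "3 channels")
  expect_error(to_grayscale(matrix(0, 4, 4)), "array")
})

test_that("cross element has 2*size - 1 foreground pixels on the midlines", {
  e1 <- cross_element(1)
  expect_identical(sum(e1$footprint), 1L)
  e3 <- cross_element(3)
  expect_identical(sum(e3$footprint), 5L)
  e17 <- cross_element(17)
  expect_identical(sum(e17$footprint), 33L)
  expect_identical(dim(e17$footprint), c(17L, 17L))
  mid <- 9L
  expect_true(all(e17$footprint[mid, ] == 1L))
  expect_true(all(e17$footprint[, mid] == 1L))
  # symmetric under quarter turns
  expect_identical(e17$footprint, t(e17$footprint)[, 17:1][17:1, ][, 17:1])
  expect_error(cross_element(4), "odd")
  expect_error(cross_element(-3), "odd")
})

test_that("closing fills a dark spot and is the identity on constants", {
  const <- matrix(120, 5, 5)
  se <- cross_element(3)
  expect_equal(gray_close(const, se), const)
  spot <- matrix(200, 5, 5)
  spot[3, 3] <- 50
  expect_true(all(gray_close(spot, se) == 200))
  th <- black_tophat(spot, se)
  expect_equal(th[3, 3], 150)
  expect_true(all(th[-13] == 0))
})

test_that("morphology matches a brute-force sliding-window oracle", {
  se <- cross_element(3)
  sq <- matrix(1L, 3, 3)  # also try a full square footprint
  for (seed in 1:25) {
    set.seed(seed)
    img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    for (fp in list(se$footprint, sq)) {
      expect_equal(gray_dilate(img, fp), naive_morph(img, fp, TRUE))
      expect_equal(gray_erode(img, fp), naive_morph(img, fp, FALSE))
      expect_equal(gray_close(img, fp), naive_close(img, fp))
    }
    # extensivity of closing and non-negativity of the top-hat
    expect_true(all(gray_close(img, se) >= img))
    expect_true(all(black_tophat(img, se) >= 0))
  }
})

test_that("hair mask thresholding is strict", {
  th <- matrix(c(0, 5, 10, 11, 150), 1, 5)
  expect_identical(as.integer(hair_mask(th, 10)), c(0L, 0L, 0L, 1L, 1L))
  expect_identical(sum(hair_mask(matrix(0, 4, 4), 10)), 0L)
  expect_identical(sum(hair_mask(matrix(255, 4, 4) - 0, 255)), 0L)
  expect_error(hair_mask(th, -1), "non-negative")
})

test_that("inpainting honors identity, constancy and locality", {
  img <- random_rgb(24, 24, seed = 4)
  empty <- matrix(0L, 24, 24)
  expect_identical(inpaint_fmm(img, empty), img)

  const <- array(77, c(16, 16, 3))
  msk <- matrix(0L, 16, 16)
  msk[5:9, 6:10] <- 1L
  expect_true(all(inpaint_fmm(const, msk) == 77))

  sub <- img[1:16, 1:16, , drop = FALSE]
  out <- inpaint_fmm(sub, msk)
  keep <- rep(msk == 0L, 3)  # untouched outside the mask, all channels
  expect_identical(out[keep], sub[keep])
  expect_error(inpaint_fmm(img, matrix(1L, 24, 24)), "whole image")
  expect_error(inpaint_fmm(img, matrix(0L, 10, 10)), "differ")
})

test_that("filled values stay within the range of nearby known pixels", {
  # horizontal ramp with a 3x3 hole
  ramp <- array(0, c(20, 20, 3))
  for (j in 1:20) ramp[, j, ] <- (j - 1) * 13
  ramp <- clamp(ramp, 0, 255)
  msk <- matrix(0L, 20, 20)
  msk[9:11, 9:11] <- 1L
  out <- inpaint_fmm(ramp, msk, inpaint_config(radius = 5))
  for (idx in which(msk == 1L)) {
    i <- (idx - 1) %% 20 + 1
    j <- (idx - 1) %/% 20 + 1
    win_i <- max(1, i - 5):min(20, i + 5)
    win_j <- max(1, j - 5):min(20, j + 5)
    known <- ramp[win_i, win_j, 1][msk[win_i, win_j] == 0L]
    expect_gte(out[i, j, 1], min(known))
    expect_lte(out[i, j, 1], max(known))
  }
})

test_that("inpainting is deterministic and integer-valued", {
  img <- random_rgb(20, 20, seed = 8)
  msk <- matrix(0L, 20, 20)
  msk[4:8, 4:16] <- 1L
  a <- inpaint_fmm(img, msk)
  b <- inpaint_fmm(img, msk)
  expect_identical(a, b)
  expect_true(all(a == round(a)))
  expect_true(all(a >= 0 & a <= 255))
})

test_that("hair removal restores a synthetically haired image", {
  cfg <- synth_config(seed = 40, n_hairs = 5)
  clean <- generate_lesion_image(cfg)$image
  hairy <- add_hair_artifacts(clean, cfg)
  res <- remove_hair(hairy$image, return_mask = TRUE)
  # detected mask covers the true strokes and inpainting moves the image
  # strictly closer to the clean original
  cover <- sum(res$hair_mask & hairy$hair_mask) / sum(hairy$hair_mask)
  expect_gte(cover, 0.8)
  expect_lt(mean(abs(res$image - clean)), mean(abs(hairy$image - clean)))
  # a hair-free image passes through almost unchanged
  res0 <- remove_hair(clean, return_mask = TRUE)
  expect_lt(mean(res0$hair_mask), 0.005)
  expect_lt(mean(abs(res0$image - clean)), 1)
})
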