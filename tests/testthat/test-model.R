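table1_rows <- function(mult = 1) {
  # encoder: layer, side, channels
  data.frame(layer = c("conv1", "pool", "conv2", "conv3", "conv4", "conv5"),
             side = c(128L, 64L, 64L, 32L, 16L, 8L),
             channels = as.integer(c(64, 64, 256, 512, 1024, 2048) * mult))
}

table2_rows <- function(mult = 1) {
  # decoder: layer, side, channels
  data.frame(layer = c("U1", "D1", "D2", "U2", "D3", "D4", "U3", "D5", "D6",
                       "U4", "D7", "D8", "U5", "D9", "D10", "output"),
             side = c(16L, 16L, 16L, 32L, 32L, 32L, 64L, 64L, 64L,
                      128L, 128L, 128L, 256L, 256L, 256L, 256L),
             channels = as.integer(c(2048, 256, 256, 256, 128, 128, 128, 64,
                                     64, 64, 32, 32, 32, 16, 16, 1 / mult) *
                                   mult))
}

test_that("the full-width model reproduces every printed layer shape", {
  model <- build_resunet(1, seed = 2)
  got <- model_shapes(model)
  for (tab in list(table1_rows(1), table2_rows(1))) {
    for (k in seq_len(nrow(tab))) {
      row <- got[got$layer == tab$layer[k], ]
      expect_identical(c(row$height, row$width, row$channels),
                       c(tab$side[k], tab$side[k], tab$channels[k]),
                       info = tab$layer[k])
    }
  }
  # exactly ten 3x3 decoder convolutions feed the 1x1 head
  dec <- grep("^D\\d+$", names(model$params), value = TRUE)
  expect_identical(sort(dec), sort(paste0("D", 1:10)))
  for (nm in dec) expect_identical(dim(model$params[[nm]]$W)[1:2], c(3L, 3L))
  expect_identical(dim(model$params$head$W), c(1L, 1L, 16L, 1L))
})

test_that("width multiplier scales channels linearly, spatial sizes fixed", {
  m4 <- build_resunet(0.25, seed = 2)
  full <- rbind(table1_rows(1), table2_rows(1))
  quarter <- model_shapes(m4)
  for (k in seq_len(nrow(full))) {
    row <- quarter[quarter$layer == full$layer[k], ]
    expect_identical(row$height, full$side[k])
    want <- if (full$layer[k] == "output") 1L else full$channels[k] %/% 4L
    expect_identical(row$channels, want)
  }
  expect_error(build_resunet(0), "positive")
  expect_error(build_resunet(-1), "positive")
})

test_that("forward emits probability maps: range, determinism, batching", {
  model <- tiny_model(seed = 5)
  set.seed(31)
  imgs <- lapply(1:3, function(i) normalize(random_rgb(256, 256, 30 + i)))
  p1 <- forward(model, imgs[[1]])
  expect_identical(dim(p1[[1]]), c(256L, 256L))
  expect_true(all(p1[[1]] >= 0 & p1[[1]] <= 1))
  p1b <- forward(model, imgs[[1]])
  expect_identical(p1[[1]], p1b[[1]])           # inference is deterministic
  batch <- forward(model, imgs)
  expect_length(batch, 3L)
  expect_equal(batch[[1]], p1[[1]], tolerance = 1e-12)  # order preserved
  expect_error(forward(model, array(0, c(128, 128, 3, 1))), "must be")
})

test_that("the realized forward shapes agree with the analytic walk", {
  model <- tiny_model(seed = 9)
  x <- array(rnorm(256 * 256 * 3), c(256, 256, 3, 1))
  f <- dermoseg:::nn_forward(model, x, keep = TRUE)
  walk <- shape_walk(model)
  for (nm in c("conv1", "conv2", "conv3", "conv4", "conv5",
               "U1", "D1", "D5", "D10", "output")) {
    id <- model$landmarks[[nm]]
    expect_identical(dim(f$acts[[id]])[1:3], as.integer(walk[[id]]),
                     info = nm)
  }
})

test_that("probability thresholding is strict and counts pixels exactly", {
  p <- matrix(0.9, 8, 8)
  expect_true(all(mask_from_prob(p, 0.5) == 1L))
  expect_true(all(mask_from_prob(matrix(0.5, 8, 8), 0.5) == 0L))
  set.seed(3)
  pm <- matrix(runif(64), 8, 8)
  expect_identical(sum(mask_from_prob(pm, 0.5)), sum(pm > 0.5))
})

test_that("predict_mask runs the full pipeline and restores resolution", {
  model <- tiny_model(seed = 11)
  img <- generate_lesion_image(synth_config(image_size = 200, seed = 3))$image
  m <- predict_mask(model, img)
  expect_identical(dim(m), c(200L, 200L))
  expect_true(all(m %in% c(0L, 1L)))
  m256 <- predict_mask(model, img, resize_back = FALSE)
  expect_identical(dim(m256), c(256L, 256L))
})

test_that("checkpoints round-trip and external encoder weights are checked", {
  model <- tiny_model(seed = 13)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  img <- normalize(random_rgb(256, 256, 77))
  expect_identical(forward(model, img)[[1]], forward(back, img)[[1]])

  # donor weights with the same architecture are accepted...
  donor <- tiny_model(seed = 99)
  enc <- donor$params[c("conv1", "conv1_bn")]
  m2 <- build_resunet(1 / 16, pretrained_encoder = enc, seed = 13)
  expect_identical(m2$params$conv1$W, donor$params$conv1$W)
  # ...mismatched shapes are not
  bad <- list(conv1 = list(W = array(0, c(3, 3, 3, 4)), b = numeric(4)))
  expect_error(build_resunet(1 / 16, pretrained_encoder = bad, seed = 1),
               "shape mismatch")
  expect_error(build_resunet(1 / 16, pretrained_encoder = list(nope = list()),
                             seed = 1), "unknown parameter")
  unlink(c(path, paste0(path, ".json")))
})
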