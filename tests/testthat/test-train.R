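test_that("config validation enforces the documented invariants", {
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(lr_reduce_factor = 1), "lr_reduce_factor")
  expect_error(train_config(lr_reduce_factor = 0), "lr_reduce_factor")
  expect_error(train_config(validation_fraction = 1), "validation_fraction")
  expect_error(train_config(loss = "mse"), "arg")
  cfg <- train_config()
  expect_identical(cfg$batch_size, 16L)
  expect_identical(cfg$learning_rate, 1e-3)
  expect_identical(cfg$max_epochs, 100L)
  expect_identical(cfg$patience, 10L)
})

test_that("rotation augmentation triples the data and keeps pairs aligned", {
  ds <- tiny_dataset(4, seed = 3, size = 64)
  aug <- augment_rotations(ds$images, ds$masks)
  expect_length(aug$images, 12L)
  expect_length(aug$masks, 12L)
  for (i in 1:4) {
    orig_img <- ds$images[[i]]
    orig_msk <- ds$masks[[i]]
    for (k in 0:2) {
      img <- aug$images[[3 * i - 2 + k]]
      msk <- aug$masks[[3 * i - 2 + k]]
      # rotation preserves the pixel multiset and the foreground count
      expect_identical(sum(msk), sum(orig_msk))
      expect_identical(sort(as.vector(img)), sort(as.vector(orig_img)))
      # mask stays aligned: lesion pixels keep their (darker) colors
      expect_identical(sort(img[, , 1][msk == 1L]),
                       sort(orig_img[, , 1][orig_msk == 1L]))
    }
    # 180 degrees is two quarter turns of the same pair
    expect_identical(aug$images[[3 * i]][, , 2],
                     dermoseg:::rot90cw(dermoseg:::rot90cw(orig_img[, , 2])))
  }
  zeros <- lapply(1:2, function(i) matrix(0L, 64, 64))
  aug0 <- augment_rotations(ds$images[1:2], zeros)
  expect_true(all(vapply(aug0$masks, sum, integer(1)) == 0L))
  expect_error(augment_rotations(ds$images, ds$masks[1:2]), "equal length")
})

test_that("a scripted plateau triggers LR reduction then early stop", {
  ds <- tiny_dataset(6, seed = 5, size = 64)
  model <- tiny_model(seed = 1)
  cfg <- train_config(batch_size = 2, learning_rate = 0, max_epochs = 60,
                      patience = 2, min_delta = 0.01, augment = FALSE,
                      seed = 9, validation_fraction = 0.17)
  res <- fit(model, ds$images, ds$masks, cfg)
  h <- as.data.frame(res$history)
  # zero learning rate: beyond batch-norm settling, validation loss cannot
  # improve by min_delta, so the LR is cut after `patience` flat epochs and
  # training stops after another `patience`, well before max_epochs
  expect_lt(attr(res$history, "stop_epoch"), 60L)
  expect_identical(nrow(h), attr(res$history, "stop_epoch"))
  expect_true(all(diff(h$lr) <= 0))  # schedule is non-increasing
})

test_that("all-background targets are learned quickly", {
  ds <- tiny_dataset(8, seed = 7, size = 64)
  zeros <- lapply(1:8, function(i) matrix(0L, 64, 64))
  model <- tiny_model(seed = 2)
  cfg <- train_config(batch_size = 2, learning_rate = 1e-2, max_epochs = 4,
                      augment = FALSE, seed = 3, validation_fraction = 0.13)
  res <- fit(model, ds$images, zeros, cfg)
  for (i in c(1, 5)) {
    p <- predict_prob(res$model, ds$images[[i]])
    expect_true(all(p < 0.5))
  }
  # training loss decreased over the run
  h <- as.data.frame(res$history)
  expect_lt(h$loss[nrow(h)], h$loss[1])
})

test_that("fit rejects unpaired or undersized datasets", {
  ds <- tiny_dataset(4, seed = 11, size = 64)
  model <- tiny_model(seed = 1)
  expect_error(fit(model, ds$images, ds$masks[1:2]), "paired")
  cfg <- train_config(batch_size = 8, augment = FALSE,
                      validation_fraction = 0.25)
  expect_error(fit(model, ds$images, ds$masks, cfg), "2 \\* batch_size")
})

test_that("training history is reproducible under a fixed seed", {
  ds <- tiny_dataset(6, seed = 13, size = 64)
  model <- tiny_model(seed = 4)
  cfg <- train_config(batch_size = 2, max_epochs = 2, augment = FALSE,
                      seed = 21, validation_fraction = 0.17)
  r1 <- fit(model, ds$images, ds$masks, cfg)
  r2 <- fit(model, ds$images, ds$masks, cfg)
  expect_equal(as.data.frame(r1$history), as.data.frame(r2$history),
               tolerance = 1e-12)
})
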