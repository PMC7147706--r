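#' Training configuration
#'
#' Defaults follow the training recipe: binary cross-entropy minimized with
#' Adam at learning rate 1e-3, batch size 16, up to 100 epochs, runtime
#' rotation augmentation, and patience-10 early stopping with one learning-rate
#' reduction.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param learning_rate initial Adam learning rate (>= 0).
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement before the
#'   learning rate is reduced (once), and again before training stops.
#' @param lr_reduce_factor multiplier in (0, 1) applied at the reduction.
#' @param min_delta smallest validation-loss decrease that counts as an
#'   improvement (guards against drift-level changes, e.g. from batch-norm
#'   running statistics settling).
#' @param loss only `"binary_crossentropy"`.
#' @param optimizer only `"adam"`.
#' @param augment triple the training set with 90/180-degree rotations.
#' @param seed seed controlling the split, shuffling and any initialization.
#' @param validation_fraction fraction of pairs held out for monitoring.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-3,
                         max_epochs = 100L, patience = 10L,
                         lr_reduce_factor = 0.1, min_delta = 1e-4,
                         loss = "binary_crossentropy", optimizer = "adam",
                         augment = TRUE, seed = 1L,
                         validation_fraction = 0.1) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1) {
    stop("lr_reduce_factor must lie in (0, 1)", call. = FALSE)
  }
  if (min_delta < 0) stop("min_delta must be non-negative", call. = FALSE)
  loss <- match.arg(loss, "binary_crossentropy")
  optimizer <- match.arg(optimizer, "adam")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_reduce_factor = lr_reduce_factor,
                 min_delta = min_delta,
                 loss = loss, optimizer = optimizer,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot_image <- function(image, times) {
  for (k in seq_len(times)) {
    image <- array(c(rot90cw(image[, , 1]), rot90cw(image[, , 2]),
                     rot90cw(image[, , 3])),
                   dim = dim(image)[c(2, 1, 3)])
  }
  image
}

#' Runtime rotation augmentation
#'
#' Returns each image/mask pair together with its 90- and 180-degree in-plane
#' rotations, tripling the dataset while keeping every mask aligned with its
#' image.
#'
#' @param images list of RGB image arrays.
#' @param masks list of binary mask matrices, same length.
#' @param seed unused (the rotations are deterministic); kept so the call
#'   signature matches the other pipeline stages.
#' @return list with `images` and `masks`, each of length `3 n`, ordered as
#'   (original, 90, 180) per input pair.
#' @export
augment_rotations <- function(images, masks, seed = NULL) {
  if (length(images) != length(masks)) {
    stop("images and masks must be paired lists of equal length",
         call. = FALSE)
  }
  out_i <- vector("list", 3L * length(images))
  out_m <- vector("list", 3L * length(masks))
  for (i in seq_along(images)) {
    img <- images[[i]]
    msk <- masks[[i]]
    out_i[[3 * i - 2]] <- img
    out_m[[3 * i - 2]] <- msk
    out_i[[3 * i - 1]] <- rot_image(img, 1L)
    out_m[[3 * i - 1]] <- as_binary_mask(rot90cw(msk))
    out_i[[3 * i]] <- rot_image(img, 2L)
    out_m[[3 * i]] <- as_binary_mask(rot90cw(rot90cw(msk)))
  }
  list(images = out_i, masks = out_m)
}

stack_batch <- function(lst, idx, channels) {
  s <- dim(lst[[idx[1]]])[1]
  array(unlist(lst[idx], use.names = FALSE),
        dim = c(s, s, channels, length(idx)))
}

bce_loss <- function(p, y, eps = 1e-7) {
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

eval_pass <- function(model, xs, ys, batch_size) {
  n <- length(xs)
  loss <- 0; acc <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    xb <- stack_batch(xs, idx, 3L)
    yb <- stack_batch(ys, idx, 1L)
    p <- nn_forward(model, xb, training = FALSE)$out
    loss <- loss + bce_loss(p, yb) * length(idx)
    acc <- acc + mean((p > 0.5) == (yb == 1)) * length(idx)
  }
  c(loss = loss / n, acc = acc / n)
}

#' Train a Res-Unet on paired images and masks
#'
#' Minimizes pixel-wise binary cross-entropy with Adam. Inputs of any size are
#' resized to the network resolution and standardized per image; the training
#' portion is optionally tripled by rotation augmentation. Validation loss is
#' monitored every epoch: after `patience` epochs without improvement the
#' learning rate is multiplied by `lr_reduce_factor` once, and after another
#' `patience` epochs without improvement training stops.
#'
#' @param model a `resunet` from [build_resunet()].
#' @param images list of RGB image arrays.
#' @param masks list of binary lesion masks, paired with `images`.
#' @param cfg a [train_config()].
#' @return list with the trained `model` and `history` (class
#'   `train_history`): a per-epoch data.frame of loss/accuracy/validation
#'   loss/validation accuracy/learning rate, plus `stop_epoch` and
#'   `lr_schedule` attributes.
#' @export
fit <- function(model, images, masks, cfg = train_config()) {
  stopifnot(inherits(model, "resunet"), inherits(cfg, "train_config"))
  if (length(images) != length(masks) || length(images) == 0L) {
    stop("images and masks must be non-empty paired lists", call. = FALSE)
  }
  local_seed(cfg$seed, {
    size <- model$input_size
    xs <- vector("list", length(images))
    ys <- vector("list", length(masks))
    for (i in seq_along(images)) {
      rp <- resize_pair(images[[i]], masks[[i]], size = size)
      xs[[i]] <- normalize(rp$image)$pixels
      ys[[i]] <- matrix(as.numeric(rp$mask), size, size)
    }

    n <- length(xs)
    n_val <- max(1L, round(cfg$validation_fraction * n))
    if (n_val >= n) stop("dataset too small for a validation split", call. = FALSE)
    val_idx <- sort(sample.int(n, n_val))
    tr_idx <- setdiff(seq_len(n), val_idx)
    xs_val <- xs[val_idx]; ys_val <- ys[val_idx]
    xs_tr <- xs[tr_idx]; ys_tr <- ys[tr_idx]
    if (cfg$augment) {
      aug <- augment_rotations(xs_tr, lapply(ys_tr, function(m) {
        as_binary_mask((m > 0) * 1L)
      }))
      # xs are normalized 3-channel arrays; rot_image handles them directly
      xs_tr <- aug$images
      ys_tr <- lapply(aug$masks, function(m) matrix(as.numeric(m), size, size))
    }
    n_tr <- length(xs_tr)
    if (n_tr < 2L * cfg$batch_size) {
      stop("need at least 2 * batch_size training pairs after augmentation",
           call. = FALSE)
    }

    state <- adam_state(model$params)
    lr <- cfg$learning_rate
    head_id <- as.character(model$landmarks$head_conv)
    t_step <- 0L
    best_val <- Inf
    bad <- 0L
    reduced <- FALSE
    hist <- vector("list", cfg$max_epochs)
    stop_epoch <- cfg$max_epochs

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n_tr)
      ep_loss <- 0; ep_acc <- 0
      for (start in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- perm[start:min(n_tr, start + cfg$batch_size - 1L)]
        xb <- stack_batch(xs_tr, idx, 3L)
        yb <- stack_batch(ys_tr, idx, 1L)
        fwd <- nn_forward(model, xb, training = TRUE, keep = TRUE)
        p <- fwd$out
        loss <- bce_loss(p, yb)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (lr = %g): aborting",
                       epoch, lr), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_acc <- ep_acc + mean((p > 0.5) == (yb == 1)) * length(idx)
        for (nm in names(fwd$bn_updates)) {
          model$params[[nm]]$rmean <- fwd$bn_updates[[nm]]$rmean
          model$params[[nm]]$rvar <- fwd$bn_updates[[nm]]$rvar
        }
        dz <- (p - yb) / length(p)
        gp <- nn_backward(model, xb, fwd$acts, fwd$caches,
                          stats::setNames(list(dz), head_id))
        rm(fwd)
        t_step <- t_step + 1L
        upd <- adam_update(model$params, gp, state, lr, t_step)
        model$params <- upd$params
        state <- upd$state
      }
      vl <- eval_pass(model, xs_val, ys_val, cfg$batch_size)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / n_tr,
                                  accuracy = ep_acc / n_tr,
                                  val_loss = vl[["loss"]],
                                  val_accuracy = vl[["acc"]], lr = lr)
      if (vl[["loss"]] < best_val - cfg$min_delta) {
        best_val <- vl[["loss"]]
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) {
          if (!reduced) {
            lr <- lr * cfg$lr_reduce_factor
            reduced <- TRUE
            bad <- 0L
          } else {
            stop_epoch <- epoch
            break
          }
        }
      }
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    stop_epoch <- min(stop_epoch, max(history$epoch))
    attr(history, "stop_epoch") <- stop_epoch
    attr(history, "lr_schedule") <- history[, c("epoch", "lr")]
    attr(history, "train_idx") <- tr_idx
    attr(history, "val_idx") <- val_idx
    class(history) <- c("train_history", class(history))
    list(model = model, history = history)
  })
}
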