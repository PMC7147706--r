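#' Build a Res-Unet segmentation model
#'
#' Constructs the encoder-decoder network: a ResNet-50 contracting path (7x7/64
#' stride-2 stem, 3x3 stride-2 max pool, then bottleneck stages with inner
#' widths 64/128/256/512, output widths 256/512/1024/2048 and repeats 3/4/6/3;
#' stride 2 sits in the first bottleneck of the last three stages, with 1x1
#' projection shortcuts on any dimension change) and a U-Net expanding path
#' (five 2x2/stride-2 transposed-convolution upsamplings U1-U5 and ten 3x3
#' convolutions D1-D10 with output widths 256,256,128,128,64,64,32,32,16,16,
#' ending in a 1x1 convolution to one channel with a sigmoid). Encoder features
#' at 16x16, 32x32, 64x64 and 128x128 (post-stem) are channel-concatenated to
#' the upsampled tensor before D1, D3, D5 and D7; the final upsampling has no
#' same-resolution encoder feature, so D9 takes no skip. Batch normalization
#' and ReLU follow every convolution on both paths. With a 256x256x3 input the
#' deepest encoder map is 8x8 with 2048 channels and the output is 256x256x1.
#'
#' @param width_multiplier positive scale applied to every channel count
#'   (1 = the full architecture; fractions give desk-scale models with the
#'   same topology and spatial shapes).
#' @param pretrained_encoder optional named list of parameter values (as
#'   produced by [save_model()]/`model$params`) used to initialize matching
#'   encoder parameters, e.g. from an externally trained model; shapes must
#'   match exactly.
#' @param seed integer seed for He-normal weight initialization.
#' @return object of class `resunet`: list with `nodes`, `params`,
#'   `landmarks`, `width_multiplier`, `input_size`, `parameter_count`.
#' @export
build_resunet <- function(width_multiplier = 1, pretrained_encoder = NULL,
                          seed = 42L) {
  if (length(width_multiplier) != 1L || !is.finite(width_multiplier) ||
      width_multiplier <= 0) {
    stop("width_multiplier must be a positive real", call. = FALSE)
  }
  ch <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  local_seed(seed, {
    g <- nn_graph()
    lm <- list()

    # --- encoder (contracting path) ---
    id <- nn_conv(g, 0L, "conv1", 7L, 3L, ch(64), stride = 2L, pad = 3L)
    id <- nn_bn(g, id, "conv1_bn", ch(64))
    id <- nn_relu(g, id)
    lm$conv1 <- id                      # 128 x 128, skip source for D7
    id <- nn_maxpool(g, id)
    lm$pool <- id                       # 64 x 64
    cin <- ch(64)

    bottleneck <- function(input, name, cin, inner, cout, stride) {
      m <- nn_conv(g, input, paste0(name, ".conv1"), 1L, cin, inner,
                   stride = stride, pad = 0L)
      m <- nn_bn(g, m, paste0(name, ".bn1"), inner)
      m <- nn_relu(g, m)
      m <- nn_conv(g, m, paste0(name, ".conv2"), 3L, inner, inner)
      m <- nn_bn(g, m, paste0(name, ".bn2"), inner)
      m <- nn_relu(g, m)
      m <- nn_conv(g, m, paste0(name, ".conv3"), 1L, inner, cout, pad = 0L)
      m <- nn_bn(g, m, paste0(name, ".bn3"), cout)
      s <- if (cin != cout || stride != 1L) {
        sc <- nn_conv(g, input, paste0(name, ".sc"), 1L, cin, cout,
                      stride = stride, pad = 0L)
        nn_bn(g, sc, paste0(name, ".sc_bn"), cout)
      } else {
        input
      }
      nn_relu(g, nn_add(g, "add", c(m, s)))
    }

    reps <- c(3L, 4L, 6L, 3L)
    for (s in 1:4) {
      inner <- ch(64 * 2^(s - 1))
      cout <- ch(256 * 2^(s - 1))
      for (b in seq_len(reps[s])) {
        stride <- if (s > 1 && b == 1L) 2L else 1L
        id <- bottleneck(id, sprintf("c%d.%d", s + 1L, b), cin, inner, cout,
                         stride)
        cin <- cout
      }
      lm[[paste0("conv", s + 1L)]] <- id   # stage outputs: 64/32/16/8 px
    }

    # --- decoder (expanding path) ---
    dec_ch <- c(256L, 256L, 128L, 128L, 64L, 64L, 32L, 32L, 16L, 16L)
    skips <- list(lm$conv4, lm$conv3, lm$conv2, lm$conv1, NULL)
    skip_ch <- c(ch(1024), ch(512), ch(256), ch(64), 0L)
    cur <- ch(2048)
    for (u in 1:5) {
      id <- nn_convt(g, id, paste0("U", u), cur, cur)
      lm[[paste0("U", u)]] <- id
      cin_d <- cur
      if (!is.null(skips[[u]])) {
        id <- nn_add(g, "concat", c(id, skips[[u]]))
        cin_d <- cur + skip_ch[u]
      }
      for (k in 1:2) {
        d <- 2L * (u - 1L) + k
        cout <- ch(dec_ch[d])
        id <- nn_conv(g, id, paste0("D", d), 3L, cin_d, cout)
        id <- nn_bn(g, id, paste0("D", d, "_bn"), cout)
        id <- nn_relu(g, id)
        lm[[paste0("D", d)]] <- id
        cin_d <- cout
        cur <- cout
      }
    }
    head <- nn_conv(g, id, "head", 1L, cur, 1L, pad = 0L)
    lm$head_conv <- head
    out <- nn_add(g, "sigmoid", head)
    lm$output <- out

    model <- structure(list(
      nodes = g$nodes,
      params = g$params,
      landmarks = lm,
      width_multiplier = width_multiplier,
      input_size = 256L,
      seed = as.integer(seed)
    ), class = "resunet")

    if (!is.null(pretrained_encoder)) {
      for (nm in names(pretrained_encoder)) {
        if (!nm %in% names(model$params)) {
          stop("unknown parameter in pretrained_encoder: ", nm, call. = FALSE)
        }
        for (f in setdiff(names(pretrained_encoder[[nm]]), "type")) {
          old <- model$params[[nm]][[f]]
          new <- pretrained_encoder[[nm]][[f]]
          if (!identical(dim(old), dim(new)) || length(old) != length(new)) {
            stop("shape mismatch for pretrained parameter ", nm, "$", f,
                 call. = FALSE)
          }
          model$params[[nm]][[f]] <- new
        }
      }
    }
    model$parameter_count <- parameter_count(model)
    model
  })
}

#' Number of learnable parameters in a model
#'
#' Counts convolution weights/biases and batch-norm scale/shift (running
#' statistics are buffers, not parameters).
#'
#' @param model a `resunet`.
#' @return integer count.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$params, function(p) {
    sum(vapply(trainable_fields(p), function(f) length(p[[f]]), numeric(1)))
  }, numeric(1)))
}

#' Analytic shape walk of a built model
#'
#' Propagates (height, width, channels) symbolically through every node of the
#' graph; used to assert that the realized architecture matches the printed
#' layer tables without running a forward pass.
#'
#' @param model a `resunet`.
#' @param input_size input side length (default the model's 256).
#' @return list of `c(h, w, c)` per node id.
#' @export
shape_walk <- function(model, input_size = model$input_size) {
  n <- length(model$nodes)
  shp <- vector("list", n)
  input <- c(input_size, input_size, 3L)
  get <- function(i) if (i == 0L) input else shp[[i]]
  for (id in seq_len(n)) {
    nd <- model$nodes[[id]]
    s <- get(nd$inputs[1])
    shp[[id]] <- switch(nd$op,
      conv = {
        w <- dim(model$params[[nd$param]]$W)
        c((s[1] + 2 * nd$pad - w[1]) %/% nd$stride + 1L,
          (s[2] + 2 * nd$pad - w[2]) %/% nd$stride + 1L, w[4])
      },
      convt = c(2L * s[1], 2L * s[2], dim(model$params[[nd$param]]$W)[4]),
      maxpool = c((s[1] + 2 * nd$pad - nd$k) %/% nd$stride + 1L,
                  (s[2] + 2 * nd$pad - nd$k) %/% nd$stride + 1L, s[3]),
      concat = {
        s2 <- get(nd$inputs[2])
        c(s[1], s[2], s[3] + s2[3])
      },
      s  # bn, relu, add, sigmoid preserve shape
    )
  }
  shp
}

#' Shapes at the architecture's landmark layers
#'
#' @param model a `resunet`.
#' @return data.frame with one row per landmark (stem, pool, the four encoder
#'   stages, U1-U5, D1-D10, output) and columns `layer`, `height`, `width`,
#'   `channels`.
#' @export
model_shapes <- function(model) {
  shp <- shape_walk(model)
  keep <- c("conv1", "pool", "conv2", "conv3", "conv4", "conv5",
            paste0("U", 1:5), paste0("D", 1:10), "output")
  rows <- lapply(keep, function(nm) as.integer(shp[[model$landmarks[[nm]]]]))
  data.frame(layer = keep,
             height = vapply(rows, `[`, integer(1), 1L),
             width = vapply(rows, `[`, integer(1), 2L),
             channels = vapply(rows, `[`, integer(1), 3L))
}

#' Forward inference to probability maps
#'
#' @param model a `resunet`.
#' @param x either a `H x W x 3 x N` array of standardized pixels, a single
#'   `normalized_image`, or a list of them; spatial size must equal the
#'   model's input size.
#' @return list of `N` probability matrices with values in `[0, 1]`.
#' @export
forward <- function(model, x) {
  if (inherits(x, "normalized_image")) x <- list(x)
  if (is.list(x)) {
    arrs <- lapply(x, function(e) {
      if (inherits(e, "normalized_image")) e$pixels else e
    })
    x <- array(unlist(arrs, use.names = FALSE),
               dim = c(dim(arrs[[1]]), length(arrs)))
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != model$input_size || dim(x)[2] != model$input_size ||
      dim(x)[3] != 3L) {
    stop(sprintf("input must be %d x %d x 3", model$input_size,
                 model$input_size), call. = FALSE)
  }
  out <- nn_forward(model, x, training = FALSE)$out
  lapply(seq_len(dim(out)[4]), function(i) out[, , 1L, i])
}

#' Probability map for one raw RGB image
#'
#' Applies the full inference pipeline: optional hair removal, resize to the
#' network resolution, per-image standardization, forward pass.
#'
#' @param model a `resunet`.
#' @param image RGB image array of any size (0-255).
#' @param dehair run [remove_hair()] first.
#' @param cfg inpainting/threshold settings for hair removal.
#' @param se_size structuring-element size for hair removal.
#' @return probability matrix at network resolution.
#' @export
predict_prob <- function(model, image, dehair = FALSE,
                         cfg = inpaint_config(), se_size = 17L) {
  assert_rgb_image(image)
  if (dehair) image <- remove_hair(image, cfg, se_size)
  rp <- resize_pair(image, size = model$input_size)
  forward(model, normalize(rp$image))[[1]]
}

#' Predict a binary lesion mask
#'
#' Thresholds the probability map (strictly greater than `threshold`) and, by
#' default, resizes the mask back to the input image's resolution with
#' nearest-neighbor interpolation.
#'
#' @inheritParams predict_prob
#' @param threshold probability cutoff in (0, 1); a pixel is lesion when its
#'   probability strictly exceeds it.
#' @param resize_back return the mask at the original image size rather than
#'   the network's 256 x 256.
#' @return integer matrix in \{0, 1\}.
#' @export
predict_mask <- function(model, image, threshold = 0.5, dehair = FALSE,
                         resize_back = TRUE, cfg = inpaint_config(),
                         se_size = 17L) {
  p <- predict_prob(model, image, dehair = dehair, cfg = cfg,
                    se_size = se_size)
  m <- mask_from_prob(p, threshold)
  if (resize_back && !all(dim(image)[1:2] == dim(m))) {
    m <- as_binary_mask(cpp_resize_nearest(m, dim(image)[1], dim(image)[2]))
  }
  m
}

#' Threshold a probability map into a binary mask
#'
#' @param prob numeric matrix in `[0, 1]`.
#' @param threshold cutoff; strictly-greater comparison, so a map equal to the
#'   threshold everywhere yields an empty mask.
#' @return integer matrix in \{0, 1\}.
#' @export
mask_from_prob <- function(prob, threshold = 0.5) {
  as_binary_mask((prob > threshold) * 1L)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameters and build settings; a JSON sidecar
#' (`<path>.json`) records the architecture spec (width multiplier, seed,
#' skip wiring, parameter count, package version) for inspection without
#' loading R.
#'
#' @param model a `resunet`.
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params,
               width_multiplier = model$width_multiplier,
               seed = model$seed), path)
  meta <- list(
    width_multiplier = model$width_multiplier,
    seed = model$seed,
    input_size = model$input_size,
    parameter_count = parameter_count(model),
    skip_wiring = list(D1 = "conv4 (16x16)", D3 = "conv3 (32x32)",
                       D5 = "conv2 (64x64)", D7 = "conv1 stem (128x128)"),
    package_version = as.character(utils::packageVersion("dermoseg"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_resunet(ck$width_multiplier, seed = ck$seed)
  if (!identical(sort(names(model$params)), sort(names(ck$params)))) {
    stop("checkpoint parameters do not match the architecture", call. = FALSE)
  }
  model$params <- ck$params
  model
}
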