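#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary matrices of identical shape.
#' @return named numeric vector with `tp`, `fp`, `tn`, `fn`; the four counts
#'   sum to the number of pixels.
#' @export
confusion <- function(pred, truth) {
  assert_mask(pred, "pred")
  assert_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth shapes differ", call. = FALSE)
  }
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Jaccard index (intersection over union)
#'
#' `TP / (TP + FP + FN)`. Two empty masks score 1 (a correct all-background
#' prediction).
#'
#' @inheritParams confusion
#' @return real in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  cf <- confusion(pred, truth)
  den <- cf[["tp"]] + cf[["fp"]] + cf[["fn"]]
  if (den == 0) 1 else cf[["tp"]] / den
}

#' Dice coefficient
#'
#' `2 TP / (2 TP + FP + FN)`; equals `2 J / (1 + J)` for the Jaccard index J
#' of the same pair. Two empty masks score 1.
#'
#' @inheritParams confusion
#' @return real in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  cf <- confusion(pred, truth)
  den <- 2 * cf[["tp"]] + cf[["fp"]] + cf[["fn"]]
  if (den == 0) 1 else 2 * cf[["tp"]] / den
}

#' Full metric record for one mask pair
#'
#' Jaccard, Dice, sensitivity (recall of the lesion class), specificity
#' (recall of the background class) and pixel accuracy. A ratio with an empty
#' denominator (e.g. sensitivity when the truth has no lesion pixel) is
#' reported as 1, the vacuous best.
#'
#' @inheritParams confusion
#' @return named numeric vector.
#' @export
segmentation_metrics <- function(pred, truth) {
  cf <- confusion(pred, truth)
  rate <- function(num, den) if (den == 0) 1 else num / den
  c(jaccard = rate(cf[["tp"]], cf[["tp"]] + cf[["fp"]] + cf[["fn"]]),
    dice = rate(2 * cf[["tp"]], 2 * cf[["tp"]] + cf[["fp"]] + cf[["fn"]]),
    sensitivity = rate(cf[["tp"]], cf[["tp"]] + cf[["fn"]]),
    specificity = rate(cf[["tn"]], cf[["tn"]] + cf[["fp"]]),
    accuracy = (cf[["tp"]] + cf[["tn"]]) / sum(cf))
}

#' Pixel-wise ROC curve with AUC
#'
#' Pools all pixels across the supplied probability maps, sweeps every
#' distinct score as a threshold (ties grouped into a single step) and
#' integrates the curve with the trapezoidal rule. The curve starts at (0, 0)
#' and ends at (1, 1).
#'
#' @param probabilities list of probability matrices (or a single matrix).
#' @param truths list of binary masks paired with `probabilities`.
#' @return object of class `roc_curve`: list with descending `thresholds`,
#'   `tpr`, `fpr` (each including the (0,0) start point as threshold `Inf`)
#'   and `auc`.
#' @export
roc <- function(probabilities, truths) {
  if (is.matrix(probabilities)) probabilities <- list(probabilities)
  if (is.matrix(truths)) truths <- list(truths)
  if (length(probabilities) != length(truths)) {
    stop("probabilities and truths must be paired", call. = FALSE)
  }
  for (i in seq_along(truths)) {
    if (!all(dim(probabilities[[i]]) == dim(truths[[i]]))) {
      stop("shape mismatch in pair ", i, call. = FALSE)
    }
  }
  s <- unlist(probabilities, use.names = FALSE)
  y <- unlist(truths, use.names = FALSE)
  P <- sum(y == 1)
  N <- sum(y == 0)
  if (P == 0 || N == 0) {
    stop("ROC undefined: all pixels belong to one class", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]
  cp <- cumsum(y[ord] == 1)
  cn <- cumsum(y[ord] == 0)
  keep <- c(which(diff(ss) != 0), length(ss))
  thresholds <- c(Inf, ss[keep])
  tpr <- c(0, cp[keep] / P)
  fpr <- c(0, cn[keep] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Evaluate a model on a paired dataset
#'
#' Predicts every image (optionally running hair removal first), computes
#' per-image metrics at the given probability threshold, aggregates them as
#' the unweighted mean over images, and builds one ROC curve from the pooled
#' pixels of all probability maps. Ground-truth masks are compared at the
#' network resolution (resized nearest-neighbor when needed).
#'
#' @param model a `resunet`.
#' @param images list of RGB image arrays.
#' @param truths list of binary lesion masks paired with `images`.
#' @param dehair run hair removal before prediction.
#' @param threshold probability cutoff for the binary masks.
#' @param cfg hair-removal settings, see [inpaint_config()].
#' @param se_size structuring-element size for hair removal.
#' @return list with `per_image` (data.frame of metrics), `aggregate` (named
#'   vector of mean metrics) and `roc` (a `roc_curve`).
#' @export
evaluate_dataset <- function(model, images, truths, dehair = FALSE,
                             threshold = 0.5, cfg = inpaint_config(),
                             se_size = 17L) {
  if (length(images) != length(truths) || length(images) == 0L) {
    stop("images and truths must be non-empty paired lists", call. = FALSE)
  }
  size <- model$input_size
  probs <- vector("list", length(images))
  ys <- vector("list", length(images))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    p <- predict_prob(model, images[[i]], dehair = dehair, cfg = cfg,
                      se_size = se_size)
    yt <- truths[[i]]
    assert_mask(yt, "truths")
    if (!all(dim(yt) == size)) {
      yt <- as_binary_mask(cpp_resize_nearest(yt, size, size))
    }
    probs[[i]] <- p
    ys[[i]] <- yt
    rows[[i]] <- segmentation_metrics(mask_from_prob(p, threshold), yt)
  }
  per_image <- as.data.frame(do.call(rbind, rows))
  per_image <- cbind(image = seq_along(images), per_image)
  aggregate <- colMeans(per_image[, -1, drop = FALSE])
  list(per_image = per_image, aggregate = aggregate, roc = roc(probs, ys))
}
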