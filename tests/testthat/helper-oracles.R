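# Independent reference implementations used to check the fast C++ paths.

# literal sliding-window grayscale morphology with edge replication
naive_morph <- function(img, footprint, dilate = TRUE) {
  H <- nrow(img); W <- ncol(img)
  fh <- nrow(footprint); fw <- ncol(footprint)
  ch <- (fh + 1) %/% 2; cw <- (fw + 1) %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      vals <- c()
      for (fi in seq_len(fh)) {
        for (fj in seq_len(fw)) {
          if (footprint[fi, fj] == 0) next
          ii <- min(max(i + fi - ch, 1), H)
          jj <- min(max(j + fj - cw, 1), W)
          vals <- c(vals, img[ii, jj])
        }
      }
      out[i, j] <- if (dilate) max(vals) else min(vals)
    }
  }
  out
}

naive_close <- function(img, footprint) {
  naive_morph(naive_morph(img, footprint, dilate = TRUE), footprint,
              dilate = FALSE)
}

# Mann-Whitney statistic: P(score_pos > score_neg) + 0.5 P(tie)
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  d <- outer(pos, neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

random_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# a desk-scale model small enough for fast unit tests
tiny_model <- function(seed = 1) build_resunet(1 / 16, seed = seed)

tiny_dataset <- function(n, seed = 1, size = 96) {
  cfg <- synth_config(image_size = size, seed = seed)
  pairs <- synth_dataset(n, cfg, with_hair = FALSE)
  list(images = lapply(pairs, `[[`, "image"),
       masks = lapply(pairs, `[[`, "mask"))
}
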