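# Training losses: focal loss on the classification branch, top-k pixel
# cross-entropy on the segmentation branch, and their (by default equally
# weighted) sum. Both heads emit unnormalised scores; softmax happens
# here for numerical control.

#' Loss configuration
#'
#' The published loss is the equally balanced sum of a focal
#' classification loss and a top-k pixel cross-entropy; the focal
#' exponent, class weights and k are not fixed by it, so the canonical
#' focal setting (gamma 2, uniform alpha) and a 10% pixel fraction are the
#' defaults, all configurable.
#'
#' @param focal_gamma focusing exponent, >= 0 (0 reduces to
#'   cross-entropy).
#' @param focal_alpha per-class weight vector (recycled), default uniform.
#' @param topk_fraction fraction of pixels kept in the segmentation loss,
#'   in `(0, 1]`; `k = ceiling(topk_fraction * n_pixels)` per image.
#' @param seg_weight,cls_weight non-negative component weights, default
#'   `(1, 1)` — the equally balanced sum.
#' @return validated config of class `loss_config`.
#' @export
loss_config <- function(focal_gamma = 2.0, focal_alpha = c(1, 1),
                        topk_fraction = 0.10, seg_weight = 1.0,
                        cls_weight = 1.0) {
  check_that(focal_gamma >= 0, "focal_gamma", "must be >= 0")
  check_that(topk_fraction > 0 && topk_fraction <= 1, "topk_fraction",
             "must lie in (0, 1]")
  check_that(seg_weight >= 0 && cls_weight >= 0, "seg_weight/cls_weight",
             "must be >= 0")
  check_that(all(focal_alpha >= 0), "focal_alpha", "must be >= 0")
  structure(list(focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 topk_fraction = topk_fraction, seg_weight = seg_weight,
                 cls_weight = cls_weight),
            class = "loss_config")
}

EPS_P <- 1e-12  # probability clamp; keeps log() finite at machine scale

#' Focal classification loss
#'
#' `FL = -alpha_y * (1 - p_y)^gamma * log(p_y)` with `p = softmax(scores)`.
#' With `gamma = 0` and uniform alpha this is the cross-entropy. Batches
#' (a matrix with one score row per item) are averaged.
#'
#' @param cls_scores numeric vector of class scores (logits), or a matrix
#'   with one row per item.
#' @param label 1-based class index (vector for batches).
#' @param config a [loss_config()].
#' @param with_grad also return the gradient w.r.t. the scores.
#' @return non-negative scalar, or `list(loss, grad)` when `with_grad`.
#' @export
focal_loss <- function(cls_scores, label, config = loss_config(),
                       with_grad = FALSE) {
  if (!is.matrix(cls_scores)) cls_scores <- matrix(cls_scores, nrow = 1)
  n <- nrow(cls_scores); k <- ncol(cls_scores)
  stopifnot(all(label %in% seq_len(k)), length(label) == n)
  alpha <- rep_len(config$focal_alpha, k)
  g <- config$focal_gamma

  losses <- numeric(n)
  grads <- if (with_grad) matrix(0, n, k) else NULL
  for (i in seq_len(n)) {
    p <- softmax_vec(cls_scores[i, ])
    y <- label[i]
    pt <- max(p[y], EPS_P)
    a <- alpha[y]
    losses[i] <- -a * (1 - pt)^g * log(pt)
    if (with_grad) {
      gl <- if (g > 0) g * (1 - pt)^(g - 1) * log(pt) else 0
      dl_dpt <- a * (gl - (1 - pt)^g / pt)
      onehot <- as.numeric(seq_len(k) == y)
      grads[i, ] <- dl_dpt * pt * (onehot - p) / n
    }
  }
  loss <- mean(losses)
  if (with_grad) list(loss = loss, grad = drop(grads)) else loss
}

# Per-pixel cross-entropy of seg scores against a binary mask.
# Returns list(ce = H x W matrix, probs = H x W x C softmax).
pixel_ce <- function(seg_scores, mask) {
  d <- dim(seg_scores)
  stopifnot(length(d) == 3, identical(d[1:2], dim(mask)))
  mx <- seg_scores[, , 1]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, seg_scores[, , c])
  es <- array(0, d); denom <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) {
    es[, , c] <- exp(seg_scores[, , c] - mx)
    denom <- denom + es[, , c]
  }
  lse <- mx + log(denom)
  cls_idx <- mask + 1L                      # background = class 1
  strue <- matrix(0, d[1], d[2])
  probs <- array(0, d)
  for (c in seq_len(d[3])) {
    sel <- cls_idx == c
    strue[sel] <- seg_scores[, , c][sel]
    probs[, , c] <- es[, , c] / denom
  }
  list(ce = lse - strue, probs = probs)
}

#' Top-k pixel cross-entropy segmentation loss
#'
#' Per-pixel softmax cross-entropy is computed for every pixel, but only
#' the `k = ceiling(topk_fraction * n_pixels)` worst-classified (largest
#' loss) pixels are averaged — and only they carry gradient. Ties at the
#' k-th value keep the first k pixels in stable descending-loss order.
#' With `topk_fraction = 1` this is the ordinary mean cross-entropy.
#'
#' @param seg_scores H x W x n_classes array of unnormalised scores.
#' @param mask binary H x W matrix (1 = lesion).
#' @param config a [loss_config()].
#' @param with_grad also return the gradient w.r.t. `seg_scores`.
#' @return non-negative scalar, or `list(loss, grad, selected)` when
#'   `with_grad` (`selected` = linear pixel indices in the top-k set).
#' @export
topk_cross_entropy <- function(seg_scores, mask, config = loss_config(),
                               with_grad = FALSE) {
  px <- pixel_ce(seg_scores, mask)
  n <- length(px$ce)
  k <- ceiling(config$topk_fraction * n)
  sel <- order(px$ce, decreasing = TRUE)[seq_len(k)]   # stable for ties
  loss <- mean(px$ce[sel])
  if (!with_grad) return(loss)
  d <- dim(seg_scores)
  grad <- array(0, d)
  cls_idx <- mask + 1L
  keep <- array(FALSE, d[1:2]); keep[sel] <- TRUE
  for (c in seq_len(d[3])) {
    gc <- (px$probs[, , c] - (cls_idx == c)) / k
    gc[!keep] <- 0
    grad[, , c] <- gc
  }
  list(loss = loss, grad = grad, selected = sel)
}

#' Combined multi-task loss
#'
#' `seg_weight * topk_cross_entropy + cls_weight * focal_loss`, defaults
#' `(1, 1)`. Both components are returned for logging, along with the head
#' gradients when requested.
#'
#' @param output a [net_forward()] result (uses `seg_scores`,
#'   `cls_logits`).
#' @param mask binary matrix congruent with the segmentation scores.
#' @param label 1-based class index (1 = low risk, 2 = high risk).
#' @param config a [loss_config()].
#' @param with_grad also return `dseg` and `dlogits`.
#' @return list with `total`, `seg`, `cls` (and gradients when requested).
#' @export
combined_loss <- function(output, mask, label, config = loss_config(),
                          with_grad = FALSE) {
  seg <- topk_cross_entropy(output$seg_scores, mask, config, with_grad)
  cls <- focal_loss(output$cls_logits, label, config, with_grad)
  if (!with_grad) {
    return(list(total = config$seg_weight * seg + config$cls_weight * cls,
                seg = seg, cls = cls))
  }
  list(total = config$seg_weight * seg$loss + config$cls_weight * cls$loss,
       seg = seg$loss, cls = cls$loss,
       dseg = config$seg_weight * seg$grad,
       dlogits = config$cls_weight * cls$grad)
}
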