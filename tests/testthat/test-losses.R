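# scores whose per-pixel cross-entropy against an all-background mask is
# exactly `ce`: CE = log(1 + exp(s2 - s1)) for true class 1
scores_with_ce <- function(ce) {
  d <- log(exp(ce) - 1)
  arr <- array(0, c(dim(ce), 2))
  arr[, , 2] <- d
  arr
}

test_that("focal loss reduces to cross-entropy and hits the worked scalars", {
  cfg0 <- loss_config(focal_gamma = 0)
  # gamma 0, uniform alpha, p_true = 0.5
  expect_equal(focal_loss(c(0, 0), 1, cfg0), log(2), tolerance = 1e-12)
  # perfect prediction
  expect_lt(focal_loss(c(50, -50), 1, loss_config()), 1e-12)
  # gamma 2, p_true = 0.25: 0.75^2 * (-log 0.25)
  s <- c(log(0.25 / 0.75), 0)
  expect_equal(focal_loss(s, 1, loss_config(focal_gamma = 2)),
               0.75^2 * -log(0.25), tolerance = 1e-9)
})

test_that("focal loss is bounded by cross-entropy for gamma > 0", {
  set.seed(1)
  for (i in 1:50) {
    s <- rnorm(2, sd = 2); y <- sample(1:2, 1)
    expect_lte(focal_loss(s, y, loss_config(focal_gamma = 2)),
               focal_loss(s, y, loss_config(focal_gamma = 0)) + 1e-12)
  }
})

test_that("focal loss averages over a batch and its gradient checks out", {
  set.seed(2)
  scores <- matrix(rnorm(6), 3, 2)
  labels <- c(1, 2, 1)
  cfg <- loss_config(focal_gamma = 2, focal_alpha = c(0.7, 1.3))
  per_item <- vapply(1:3, function(i) focal_loss(scores[i, ], labels[i], cfg),
                     numeric(1))
  expect_equal(focal_loss(scores, labels, cfg), mean(per_item))
  fg <- focal_loss(scores, labels, cfg, with_grad = TRUE)
  eps <- 1e-6
  for (i in seq_along(scores)) {
    s1 <- scores; s1[i] <- s1[i] + eps
    s2 <- scores; s2[i] <- s2[i] - eps
    num <- (focal_loss(s1, labels, cfg) - focal_loss(s2, labels, cfg)) /
      (2 * eps)
    expect_lt(abs(num - fg$grad[i]), 1e-6)
  }
})

test_that("top-k with fraction 1 equals the mean pixel cross-entropy", {
  set.seed(3)
  s <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(topk_cross_entropy(s, m, loss_config(topk_fraction = 1)),
               mean(oracle_pixel_ce(s, m)), tolerance = 1e-9)
})

test_that("the engineered 2x2 instance selects the two worst pixels", {
  ce <- matrix(c(0.1, 0.2, 0.7, 1.0), 2, 2)
  s <- scores_with_ce(ce)
  m <- matrix(0L, 2, 2)
  expect_equal(topk_cross_entropy(s, m, loss_config(topk_fraction = 0.5)),
               (0.7 + 1.0) / 2, tolerance = 1e-9)
  # near-perfect prediction drives the loss to ~0
  good <- array(0, c(2, 2, 2)); good[, , 1] <- 20
  expect_lt(topk_cross_entropy(good, m, loss_config()), 1e-3)
})

test_that("top-k equals the explicit-sort brute-force oracle", {
  set.seed(4)
  for (i in 1:60) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    s <- array(rnorm(h * w * 2, sd = 2), c(h, w, 2))
    m <- matrix(rbinom(h * w, 1, runif(1, 0.1, 0.9)), h, w)
    frac <- runif(1, 0.05, 1)
    expect_equal(topk_cross_entropy(s, m, loss_config(topk_fraction = frac)),
                 oracle_topk_ce(s, m, frac), tolerance = 1e-6)
  }
})

test_that("the top-k average is monotone non-increasing in k", {
  set.seed(5)
  s <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  m <- matrix(rbinom(36, 1, 0.3), 6, 6)
  losses <- vapply(1:36, function(k) {
    topk_cross_entropy(s, m, loss_config(topk_fraction = k / 36))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("gradient flows only through the selected top-k pixels", {
  set.seed(6)
  s <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  m <- matrix(rbinom(16, 1, 0.4), 4, 4)
  cfg <- loss_config(topk_fraction = 0.25)       # k = 4 of 16
  res <- topk_cross_entropy(s, m, cfg, with_grad = TRUE)
  outside <- setdiff(seq_len(16), res$selected)
  # analytic gradient is exactly zero outside the selection
  for (c in 1:2) {
    expect_true(all(res$grad[, , c][outside] == 0))
  }
  # perturbing a non-selected pixel leaves loss and selected-set gradient
  # unchanged (finite-difference confirmation)
  i <- outside[1]
  s2 <- s
  s2[, , 1][i] <- s2[, , 1][i] - 1e-3            # make it even easier
  res2 <- topk_cross_entropy(s2, m, cfg, with_grad = TRUE)
  expect_equal(res2$loss, res$loss, tolerance = 1e-12)
  expect_equal(res2$grad, res$grad, tolerance = 1e-12)
  # and the analytic gradient matches finite differences on selected pixels
  eps <- 1e-6
  for (i in res$selected[1:2]) {
    sp <- s; sp[, , 2][i] <- sp[, , 2][i] + eps
    sm <- s; sm[, , 2][i] <- sm[, , 2][i] - eps
    num <- (topk_cross_entropy(sp, m, cfg) -
              topk_cross_entropy(sm, m, cfg)) / (2 * eps)
    expect_lt(abs(num - res$grad[, , 2][i]), 1e-5)
  }
})

test_that("ties at the k-th value resolve by stable index order", {
  s <- array(0, c(2, 2, 2))                      # all pixels tie at log 2
  m <- matrix(0L, 2, 2)
  res <- topk_cross_entropy(s, m, loss_config(topk_fraction = 0.5),
                            with_grad = TRUE)
  expect_identical(res$selected, 1:2)            # first two in index order
  expect_equal(res$loss, log(2))
})

test_that("the combined loss is the weighted sum of its components", {
  set.seed(7)
  out <- list(seg_scores = array(rnorm(32), c(4, 4, 2)),
              cls_logits = rnorm(2))
  m <- matrix(rbinom(16, 1, 0.5), 4, 4)
  cfg <- loss_config(seg_weight = 1, cls_weight = 1)
  cl <- combined_loss(out, m, 2, cfg)
  expect_equal(cl$total, cl$seg + cl$cls, tolerance = 1e-9)
  cfg0 <- loss_config(cls_weight = 0)
  expect_equal(combined_loss(out, m, 2, cfg0)$total,
               combined_loss(out, m, 2, cfg0)$seg)
  # both components zero => total zero
  perfect <- list(seg_scores = scores_with_ce(matrix(1e-9, 4, 4)),
                  cls_logits = c(-60, 60))
  expect_lt(combined_loss(perfect, matrix(0L, 4, 4), 2, cfg)$total, 1e-6)
})

test_that("loss config invariants are enforced", {
  expect_error(loss_config(topk_fraction = 0), "topk_fraction")
  expect_error(loss_config(focal_gamma = -1), "focal_gamma")
  expect_error(loss_config(seg_weight = -1), "weight")
})
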