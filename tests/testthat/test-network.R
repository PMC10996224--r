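test_that("segmentation output matches the input spatial shape", {
  net <- tiny_network(depth = 3, base = 4, input = 32)
  out <- net_forward(net, matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(out$seg_scores), c(32L, 32L, 2L))
  # fully convolutional: another admissible size works on the same weights
  out2 <- net_forward(net, matrix(runif(64 * 64), 64, 64))
  expect_identical(dim(out2$seg_scores), c(64L, 64L, 2L))
  expect_error(net_forward(net, matrix(runif(30 * 30), 30, 30)),
               "divisible")
  expect_error(network_config(depth = 5, input_size = 100), "input_size")
})

test_that("class probabilities are a softmax for random weights", {
  for (s in 1:100) {
    net <- tiny_network(depth = 2, base = 2, input = 8, seed = s)
    out <- net_forward(net, matrix(runif(64), 8, 8))
    expect_lt(abs(sum(out$cls_probs) - 1), 1e-6)
    expect_true(all(out$cls_probs >= 0))
  }
})

test_that("all-zero weights yield the symmetric (0.5, 0.5) classification", {
  net <- tiny_network(depth = 2, base = 2, input = 8)
  net$params <- lapply(net$params, function(p) p * 0)
  out <- net_forward(net, matrix(runif(64), 8, 8))
  expect_equal(out$cls_probs, c(0.5, 0.5))
  expect_true(all(out$seg_scores == 0))
})

test_that("parameter count matches a layer-by-layer closed form (depth 3, base 8)", {
  # independent arithmetic: channels 8, 16, 32 at levels 1..3
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  expected <-
    conv(3, 1, 8) + conv(3, 8, 8) +          # encoder level 1
    conv(3, 8, 16) + conv(3, 16, 16) +       # encoder level 2
    conv(3, 16, 32) + conv(3, 32, 32) +      # bottleneck
    conv(3, 32, 32) +                        # cls: single conv
    conv(3, 32, 32) + conv(3, 32, 32) +      # cls: double block
    conv(1, 32, 2) +                         # cls: output conv
    conv(3, 32 + 16, 16) + conv(3, 16, 16) + # decoder level 2
    conv(3, 16 + 8, 8) + conv(3, 8, 8) +     # decoder level 1
    conv(3, 8, 8) + conv(3, 8, 8) +          # seg head convs
    conv(1, 8, 2)                            # seg output conv
  net <- build_network(network_config(depth = 3, base_channels = 8,
                                      input_size = 32))
  expect_equal(count_params(net), expected)
})

test_that("inference is deterministic given weights and input", {
  net <- tiny_network(depth = 2, base = 2, input = 16, seed = 3)
  x <- matrix(runif(256), 16, 16)
  o1 <- net_forward(net, x)
  o2 <- net_forward(net, x)
  expect_identical(o1$seg_scores, o2$seg_scores)
  expect_identical(o1$cls_probs, o2$cls_probs)
})

test_that("the backward pass matches finite differences", {
  net <- tiny_network(depth = 2, base = 2, input = 8, seed = 4)
  set.seed(5)
  # randomise biases: zero biases leave many pre-activations exactly on
  # the ReLU kink, where central differences measure half-sided slopes
  for (nm in grep("_b$", names(net$params), value = TRUE)) {
    net$params[[nm]] <- rnorm(length(net$params[[nm]]), 0, 0.3)
  }
  x <- matrix(runif(64), 8, 8)
  mask <- matrix(rbinom(64, 1, 0.3), 8, 8)
  lc <- loss_config(topk_fraction = 0.5)
  out <- net_forward(net, x, with_cache = TRUE)
  ls <- combined_loss(out, mask, 2, lc, with_grad = TRUE)
  g <- net_backward(net, out$cache, ls$dseg, ls$dlogits)
  expect_setequal(names(g), names(net$params))
  loss_at <- function(nm, i, v) {
    n2 <- net
    n2$params[[nm]][i] <- v
    combined_loss(net_forward(n2, x), mask, 2, lc)$total
  }
  for (nm in sample(names(net$params), 12)) {
    i <- sample(length(net$params[[nm]]), 1)
    v0 <- net$params[[nm]][i]
    eps <- 1e-5
    num <- (loss_at(nm, i, v0 + eps) - loss_at(nm, i, v0 - eps)) / (2 * eps)
    expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num), abs(g[[nm]][i])),
              1e-4, label = nm)
  }
})

test_that("every trainable parameter receives gradient somewhere", {
  net <- tiny_network(depth = 2, base = 2, input = 8, seed = 6)
  total <- lapply(net$params, function(p) p * 0)
  set.seed(7)
  for (trial in 1:4) {
    x <- matrix(runif(64), 8, 8)
    mask <- matrix(rbinom(64, 1, 0.5), 8, 8)
    out <- net_forward(net, x, with_cache = TRUE)
    ls <- combined_loss(out, mask, sample(1:2, 1), loss_config(),
                        with_grad = TRUE)
    g <- net_backward(net, out$cache, ls$dseg, ls$dlogits)
    total <- Map(function(a, b) abs(a) + abs(b), total, g)
  }
  for (nm in names(total)) {
    expect_gt(max(total[[nm]]), 0, label = nm)
  }
})

test_that("checkpoints round trip with a version stamp", {
  net <- tiny_network(depth = 2, base = 2, input = 8, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  rt <- load_checkpoint(path)
  expect_equal(rt$params, net$params)
  expect_equal(rt$config, net$config)
  bad <- list(version = "other", params = net$params, config = net$config)
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "version")
})
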