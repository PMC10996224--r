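# The dual-branch fully convolutional network.
#
# Canonical U-Net encoder-decoder (two 3x3 convolutions + ReLU per block,
# 2x2 max pooling down, bilinear 2x interpolation up, skip concatenation)
# with two heads: a segmentation head of two 3x3 conv+ReLU layers and a
# 1x1 score layer, and a classification branch reading the bottleneck
# feature map through one 3x3 conv, a double 3x3 conv block, a 1x1 score
# layer, global average pooling and softmax.
#
# The forward pass stores exactly the activations the mirrored
# hand-written backward pass needs (block inputs and post-ReLU maps); the
# backward pass is verified against finite differences in the test suite.

#' Network architecture configuration
#'
#' @param depth number of resolution levels; depth 5 performs four
#'   halvings.
#' @param base_channels channels at the first level, doubling per level.
#' @param n_seg_classes,n_cls_classes output classes (2 and 2).
#' @param input_size expected input side; must be divisible by
#'   `2^(depth - 1)`. Any admissible size is accepted at run time (the
#'   network is fully convolutional).
#' @return validated config of class `network_config`.
#' @export
network_config <- function(depth = 5, base_channels = 64, n_seg_classes = 2,
                           n_cls_classes = 2, input_size = 1024) {
  check_that(depth >= 2, "depth", "must be >= 2")
  check_that(base_channels >= 1, "base_channels", "must be >= 1")
  check_that(input_size %% 2^(depth - 1) == 0, "input_size",
             sprintf("must be divisible by 2^(depth-1) = %d", 2^(depth - 1)))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_seg_classes = as.integer(n_seg_classes),
                 n_cls_classes = as.integer(n_cls_classes),
                 input_size = as.integer(input_size),
                 upsampling = "bilinear"),
            class = "network_config")
}

# Layer table: name, kernel, in/out channels, in declaration order.
layer_plan <- function(config) {
  d <- config$depth
  ch <- config$base_channels * 2^(0:(d - 1))
  rows <- list()
  add <- function(name, k, cin, cout) {
    rows[[length(rows) + 1]] <<- data.frame(name = name, k = k, cin = cin,
                                            cout = cout)
  }
  for (l in seq_len(d - 1)) {
    cin <- if (l == 1) 1 else ch[l - 1]
    add(sprintf("enc%d_c1", l), 3, cin, ch[l])
    add(sprintf("enc%d_c2", l), 3, ch[l], ch[l])
  }
  add("bott_c1", 3, ch[d - 1], ch[d])
  add("bott_c2", 3, ch[d], ch[d])
  add("cls1", 3, ch[d], ch[d])
  add("clsd_c1", 3, ch[d], ch[d])
  add("clsd_c2", 3, ch[d], ch[d])
  add("cls_out", 1, ch[d], config$n_cls_classes)
  for (l in rev(seq_len(d - 1))) {
    add(sprintf("dec%d_c1", l), 3, ch[l + 1] + ch[l], ch[l])
    add(sprintf("dec%d_c2", l), 3, ch[l], ch[l])
  }
  add("segd_c1", 3, ch[1], ch[1])
  add("segd_c2", 3, ch[1], ch[1])
  add("seg_out", 1, ch[1], config$n_seg_classes)
  do.call(rbind, rows)
}

#' Build (initialise) the dual-branch network
#'
#' Weights use He (Kaiming) initialisation, `sd = sqrt(2 / fan_in)`;
#' biases start at zero. Deterministic given `seed`.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `dcis_network` holding `params` and `config`.
#' @export
build_network <- function(config, seed = 1) {
  plan <- layer_plan(config)
  params <- with_seed(seed, {
    p <- list()
    for (i in seq_len(nrow(plan))) {
      k <- plan$k[i]; cin <- plan$cin[i]; cout <- plan$cout[i]
      p[[paste0(plan$name[i], "_w")]] <-
        array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              c(k, k, cin, cout))
      p[[paste0(plan$name[i], "_b")]] <- numeric(cout)
    }
    p
  })
  structure(list(params = params, config = config, version = "dcisnet-1"),
            class = "dcis_network")
}

#' Total number of trainable parameters
#' @param network a `dcis_network`.
#' @return integer count of weights plus biases.
#' @export
count_params <- function(network) {
  sum(vapply(network$params, length, numeric(1)))
}

#' @export
print.dcis_network <- function(x, ...) {
  cat(sprintf("<dcis_network> depth %d, base %d channels, %s parameters\n",
              x$config$depth, x$config$base_channels,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

conv_f <- function(x, p, nm) {
  cpp_conv2d_forward(x, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]])
}

dconv_f <- function(x, p, nm) {
  a1 <- relu(conv_f(x, p, paste0(nm, "_c1")))
  a2 <- relu(conv_f(a1, p, paste0(nm, "_c2")))
  list(out = a2, cache = list(x = x, a1 = a1, a2 = a2))
}

concat3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Forward pass
#'
#' Fully convolutional: any input whose sides are divisible by
#' `2^(depth - 1)` is admissible and yields per-pixel segmentation scores
#' of identical spatial size. Deterministic given weights and input.
#'
#' @param network a `dcis_network`.
#' @param x numeric matrix (H x W) with values in `[0, 1]`, or an
#'   `H x W x 1` array.
#' @param with_cache keep intermediate activations for [net_backward()].
#' @return list with `seg_scores` (H x W x n_seg_classes, unnormalised),
#'   `cls_logits`, `cls_probs` (softmax over logits), and `cache` (or
#'   `NULL`).
#' @export
net_forward <- function(network, x, with_cache = FALSE) {
  p <- network$params
  d <- network$config$depth
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 1)
  if (any(dim(x)[1:2] %% 2^(d - 1) != 0)) {
    stop(sprintf("input %dx%d not divisible by 2^(depth-1) = %d",
                 dim(x)[1], dim(x)[2], 2^(d - 1)), call. = FALSE)
  }
  cache <- if (with_cache) list(enc = vector("list", d - 1),
                                dec = vector("list", d - 1)) else NULL
  skips <- vector("list", d - 1)
  h <- x
  for (l in seq_len(d - 1)) {
    f <- dconv_f(h, p, sprintf("enc%d", l))
    skips[[l]] <- f$out
    mp <- cpp_maxpool2_forward(f$out)
    if (with_cache) cache$enc[[l]] <- list(dc = f$cache, idx = mp$idx,
                                           dim = dim(f$out))
    h <- mp$y
  }
  bt <- dconv_f(h, p, "bott")
  B <- bt$out
  if (with_cache) cache$bott <- bt$cache

  # classification branch off the bottleneck
  c1 <- relu(conv_f(B, p, "cls1"))
  cd <- dconv_f(c1, p, "clsd")
  cmap <- conv_f(cd$out, p, "cls_out")
  logits <- apply(cmap, 3, mean)
  probs <- softmax_vec(logits)
  if (with_cache) cache$cls <- list(B = B, c1 = c1, dc = cd$cache,
                                    map_in = cd$out, map_dim = dim(cmap))

  # decoder
  dd <- B
  for (l in rev(seq_len(d - 1))) {
    u <- cpp_upsample2_forward(dd)
    cat3 <- concat3(skips[[l]], u)
    f <- dconv_f(cat3, p, sprintf("dec%d", l))
    if (with_cache) cache$dec[[l]] <- list(dc = f$cache,
                                           ch_skip = dim(skips[[l]])[3])
    dd <- f$out
  }

  # segmentation head
  sd <- dconv_f(dd, p, "segd")
  seg <- conv_f(sd$out, p, "seg_out")
  if (with_cache) cache$seg <- list(dc = sd$cache, head_in = dd)

  list(seg_scores = seg, cls_logits = logits, cls_probs = probs,
       cache = cache)
}

# Backward through a double-conv block; accumulates weight gradients into
# environment `ge` and returns the gradient w.r.t. the block input.
dconv_b <- function(dout, p, nm, cc, ge) {
  n2 <- paste0(nm, "_c2"); n1 <- paste0(nm, "_c1")
  dz2 <- dout * (cc$a2 > 0)
  bk2 <- cpp_conv2d_backward(cc$a1, p[[paste0(n2, "_w")]], dz2)
  dz1 <- bk2$dx * (cc$a1 > 0)
  bk1 <- cpp_conv2d_backward(cc$x, p[[paste0(n1, "_w")]], dz1)
  acc_grad(ge, n2, bk2); acc_grad(ge, n1, bk1)
  bk1$dx
}

acc_grad <- function(ge, nm, bk) {
  wn <- paste0(nm, "_w"); bn <- paste0(nm, "_b")
  ge[[wn]] <- if (is.null(ge[[wn]])) bk$dw else ge[[wn]] + bk$dw
  ge[[bn]] <- if (is.null(ge[[bn]])) bk$db else ge[[bn]] + bk$db
}

#' Backward pass
#'
#' Propagates head gradients to every trainable parameter.
#'
#' @param network a `dcis_network`.
#' @param cache the cache from `net_forward(..., with_cache = TRUE)`.
#' @param dseg gradient of the loss w.r.t. `seg_scores` (same shape).
#' @param dlogits gradient of the loss w.r.t. `cls_logits`.
#' @return named list of gradients matching `network$params`.
#' @export
net_backward <- function(network, cache, dseg, dlogits) {
  p <- network$params
  d <- network$config$depth
  ge <- new.env(parent = emptyenv())

  # segmentation head
  bko <- cpp_conv2d_backward(cache$seg$dc$a2, p$seg_out_w, dseg)
  acc_grad(ge, "seg_out", bko)
  ddec1 <- dconv_b(bko$dx, p, "segd", cache$seg$dc, ge)

  # classification branch
  md <- cache$cls$map_dim
  dcmap <- array(rep(dlogits / (md[1] * md[2]), each = md[1] * md[2]), md)
  bkc <- cpp_conv2d_backward(cache$cls$map_in, p$cls_out_w, dcmap)
  acc_grad(ge, "cls_out", bkc)
  dc1 <- dconv_b(bkc$dx, p, "clsd", cache$cls$dc, ge)
  dz <- dc1 * (cache$cls$c1 > 0)
  bk1 <- cpp_conv2d_backward(cache$cls$B, p$cls1_w, dz)
  acc_grad(ge, "cls1", bk1)
  dB_cls <- bk1$dx

  # decoder (reverse of forward order: dec1 first)
  dskips <- vector("list", d - 1)
  dcur <- ddec1
  for (l in seq_len(d - 1)) {
    cc <- cache$dec[[l]]
    dcat <- dconv_b(dcur, p, sprintf("dec%d", l), cc$dc, ge)
    ks <- cc$ch_skip
    dskips[[l]] <- dcat[, , seq_len(ks), drop = FALSE]
    du <- dcat[, , (ks + 1):dim(dcat)[3], drop = FALSE]
    dcur <- cpp_upsample2_backward(du)
  }

  # bottleneck (decoder grad + classification branch grad)
  dh <- dconv_b(dcur + dB_cls, p, "bott", cache$bott, ge)

  # encoder, deepest level first
  for (l in rev(seq_len(d - 1))) {
    cc <- cache$enc[[l]]
    dpool <- cpp_maxpool2_backward(cc$idx, dh, cc$dim[1], cc$dim[2], cc$dim[3])
    dh <- dconv_b(dpool + dskips[[l]], p, sprintf("enc%d", l), cc$dc, ge)
  }

  out <- as.list(ge)
  # zero gradients are legitimate (all-negative pre-activations); ensure
  # every parameter has an entry
  for (nm in names(p)) if (is.null(out[[nm]])) out[[nm]] <- p[[nm]] * 0
  out[names(p)]
}

#' Save / load a network checkpoint
#'
#' Checkpoints carry the weights, the full architecture config, and a
#' format version stamp. Binary RDS — a run-time artifact, not a source
#' format.
#'
#' @param network a `dcis_network`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `dcis_network`.
#' @export
save_checkpoint <- function(network, path) {
  saveRDS(list(version = network$version, config = network$config,
               params = network$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "dcisnet-1")) {
    stop("unsupported checkpoint version '", x$version, "'", call. = FALSE)
  }
  structure(list(params = x$params, config = x$config, version = x$version),
            class = "dcis_network")
}
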