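# Preprocessing and training-time augmentation.
#
# Composition order follows the preprocessing narrative: vendor LUT ->
# linear rescale to [0,1] -> lesion-centred crop (randomly perturbed in
# training) -> horizontal flip -> gamma -> additive Gaussian noise.
# Geometric operations are applied identically to image and mask;
# photometric operations never touch the mask.

#' Augmentation configuration
#'
#' Defaults are the published preprocessing constants: 1024 x 1024 crops
#' around the lesion center perturbed by at most 150 px per axis,
#' horizontal flip with p = 0.5, gamma in \[0.95, 1.05\], additive Gaussian
#' noise with magnitude at most 5% of the unit intensity scale, and a
#' randomly chosen vendor lookup table.
#'
#' @param crop_size crop side in pixels, divisible by 16.
#' @param max_perturb maximum lesion-center perturbation per axis
#'   (< `crop_size / 2`, which guarantees the lesion center stays inside
#'   the crop).
#' @param flip_p horizontal flip probability.
#' @param gamma_range positive interval for the gamma exponent.
#' @param noise_max_frac upper bound of the noise standard deviation on the
#'   `[0, 1]` intensity scale, in `[0, 1)`.
#' @param randomize_lut apply a randomly chosen LUT during training.
#' @param seed integer seed for standalone use of the pipeline.
#' @return validated config of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_size = 1024, max_perturb = 150,
                                flip_p = 0.5, gamma_range = c(0.95, 1.05),
                                noise_max_frac = 0.05, randomize_lut = TRUE,
                                seed = 1) {
  check_that(crop_size > 0 && crop_size %% 16 == 0, "crop_size",
             "must be positive and divisible by 16")
  check_that(max_perturb >= 0 && max_perturb < crop_size / 2, "max_perturb",
             "must satisfy 0 <= max_perturb < crop_size/2")
  check_that(flip_p >= 0 && flip_p <= 1, "flip_p", "must lie in [0, 1]")
  check_that(all(gamma_range > 0) && length(gamma_range) == 2,
             "gamma_range", "must be a positive interval")
  check_that(noise_max_frac >= 0 && noise_max_frac < 1, "noise_max_frac",
             "must lie in [0, 1)")
  structure(list(crop_size = as.integer(crop_size),
                 max_perturb = as.integer(max_perturb), flip_p = flip_p,
                 gamma_range = gamma_range, noise_max_frac = noise_max_frac,
                 randomize_lut = isTRUE(randomize_lut),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Apply one randomly chosen vendor LUT
#'
#' A LUT is chosen uniformly from the sample's family and applied
#' pointwise; with no family (or `randomize_lut = FALSE`) the image passes
#' through unchanged. Consumes the R RNG stream.
#'
#' @param sample a [mammogram_sample()].
#' @param randomize draw a LUT (training) or pass through (evaluation).
#' @return numeric image matrix.
#' @export
apply_random_lut <- function(sample, randomize = TRUE) {
  if (!randomize || !length(sample$lut_family)) return(sample$image)
  lut <- sample$lut_family[[sample.int(length(sample$lut_family), 1)]]
  apply_lut(sample$image, lut)
}

#' Linearly rescale an image to the unit interval
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros (the
#' degenerate-input convention, avoiding division by zero).
#'
#' @param image numeric matrix.
#' @return matrix with values in `[0, 1]`.
#' @export
rescale_unit <- function(image) {
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Crop a lesion-centred window from image and mask
#'
#' A `crop_size` square is taken around the lesion center; in training
#' mode the center is first shifted by integer offsets drawn uniformly and
#' independently per axis from `[-max_perturb, max_perturb]`. Regions
#' falling outside the image are zero-padded (mammographic background is
#' near zero). The lesion center lands at crop pixel
#' `(crop_size/2, crop_size/2)` (0-based) when unperturbed.
#'
#' @param image,mask congruent matrices.
#' @param center `(row, col)` 0-based lesion center inside the image.
#' @param config an [augmentation_config()].
#' @param train_mode draw a random perturbation (consumes the RNG).
#' @return list with cropped `image` and `mask`.
#' @export
crop_lesion <- function(image, mask, center, config, train_mode = FALSE) {
  if (any(center < 0) || center[1] > nrow(image) - 1 ||
      center[2] > ncol(image) - 1) {
    stop("lesion center outside image", call. = FALSE)
  }
  s <- config$crop_size
  delta <- if (train_mode && config$max_perturb > 0) {
    sample(seq(-config$max_perturb, config$max_perturb), 2, replace = TRUE)
  } else c(0L, 0L)
  start <- round(center) + delta - s %/% 2       # 0-based window start
  out_i <- matrix(0, s, s)
  out_m <- matrix(0L, s, s)
  src_r <- (max(0, start[1])):(min(nrow(image) - 1, start[1] + s - 1))
  src_c <- (max(0, start[2])):(min(ncol(image) - 1, start[2] + s - 1))
  if (length(src_r) > 0 && length(src_c) > 0 && src_r[1] <= src_r[length(src_r)]) {
    dst_r <- src_r - start[1] + 1
    dst_c <- src_c - start[2] + 1
    out_i[dst_r, dst_c] <- image[src_r + 1, src_c + 1]
    out_m[dst_r, dst_c] <- mask[src_r + 1, src_c + 1]
  }
  list(image = out_i, mask = out_m)
}

#' Mirror image and mask along columns
#' @param image,mask congruent matrices.
#' @return list with flipped `image` and `mask`.
#' @export
hflip <- function(image, mask) {
  list(image = image[, ncol(image):1, drop = FALSE],
       mask = mask[, ncol(mask):1, drop = FALSE])
}

#' Random horizontal flip applied to both image and mask
#'
#' With probability `p` both arrays are mirrored along columns — always
#' both or neither. Consumes the R RNG stream.
#'
#' @inheritParams hflip
#' @param p flip probability.
#' @return list with `image`, `mask`, and logical `flipped`.
#' @export
random_hflip <- function(image, mask, p = 0.5) {
  if (runif(1) < p) c(hflip(image, mask), flipped = TRUE)
  else list(image = image, mask = mask, flipped = FALSE)
}

#' Random gamma transform
#'
#' `image ^ gamma` with gamma drawn uniformly from `gamma_range`; the unit
#' interval endpoints are fixed points and pixel ordering is preserved.
#' The mask is untouched by construction. Consumes the R RNG stream.
#'
#' @param image matrix with values in `[0, 1]`.
#' @param gamma_range positive interval.
#' @return transformed image.
#' @export
random_gamma <- function(image, gamma_range = c(0.95, 1.05)) {
  image ^ runif(1, gamma_range[1], gamma_range[2])
}

#' Additive Gaussian noise with randomly drawn magnitude
#'
#' The noise standard deviation is drawn uniformly from
#' `[0, noise_max_frac]` on the unit intensity scale ("magnitude at most
#' 5%" under the global-scale reading); i.i.d. zero-mean Gaussian noise is
#' added per pixel and the result clipped back to `[0, 1]`. Consumes the
#' R RNG stream.
#'
#' @param image matrix with values in `[0, 1]`.
#' @param noise_max_frac upper bound for the drawn standard deviation.
#' @return noisy image in `[0, 1]`.
#' @export
add_gaussian_noise <- function(image, noise_max_frac = 0.05) {
  if (noise_max_frac == 0) return(image)
  sigma <- runif(1, 0, noise_max_frac)
  clamp(image + rnorm(length(image), 0, sigma), 0, 1)
}

#' Full stochastic training transform
#'
#' LUT -> rescale -> perturbed crop -> flip -> gamma -> noise, in that
#' order. Deterministic given the R RNG state.
#'
#' @param sample a [mammogram_sample()].
#' @param mask binary matrix congruent with the sample image.
#' @param config an [augmentation_config()].
#' @return list with augmented `image` (in `[0, 1]`, `crop_size` square)
#'   and congruent binary `mask`.
#' @export
train_transform <- function(sample, mask, config) {
  img <- apply_random_lut(sample, config$randomize_lut)
  img <- rescale_unit(img)
  cr <- crop_lesion(img, mask, sample$lesion_center, config, train_mode = TRUE)
  fl <- random_hflip(cr$image, cr$mask, config$flip_p)
  img <- random_gamma(fl$image, config$gamma_range)
  img <- add_gaussian_noise(img, config$noise_max_frac)
  list(image = img, mask = fl$mask)
}

#' Deterministic evaluation transform
#'
#' Identity LUT, rescale to `[0, 1]`, centred (unperturbed) crop; no
#' stochastic steps, hence idempotent on its own output geometry.
#'
#' @inheritParams train_transform
#' @return list with `image` and `mask`.
#' @export
eval_transform <- function(sample, mask, config) {
  img <- rescale_unit(sample$image)
  crop_lesion(img, mask, sample$lesion_center, config, train_mode = FALSE)
}
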