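make_sample <- function(n = 64, seed = 1, luts = NULL, center = NULL) {
  set.seed(seed)
  img <- matrix(sample(0:4095, n * n, replace = TRUE), n, n)
  if (is.null(center)) center <- c(n %/% 2, n %/% 2)
  mammogram_sample(img, "P1", "CC", "L", center, lut_family = luts)
}

test_that("augmentation config invariants are enforced", {
  expect_error(augmentation_config(crop_size = 100), "crop_size")
  expect_error(augmentation_config(crop_size = 64, max_perturb = 32),
               "max_perturb")
  expect_error(augmentation_config(noise_max_frac = 1), "noise_max_frac")
  expect_error(augmentation_config(gamma_range = c(-1, 1)), "gamma_range")
})

test_that("LUT randomisation is uniform-choice, monotone, and seeded", {
  ident <- new_lut(0, 0:4095)
  s <- make_sample(16, luts = list(ident))
  set.seed(1)
  expect_equal(apply_random_lut(s), s$image, ignore_attr = TRUE)

  lut <- new_lut(0, round(cumsum(runif(4096, 0, 2))))
  s2 <- make_sample(16, luts = list(lut))
  set.seed(2)
  out <- apply_random_lut(s2)
  ord <- order(as.vector(s2$image))
  expect_true(all(diff(as.vector(out)[ord]) >= 0))  # x<=y => lut(x)<=lut(y)

  two <- make_sample(16, luts = list(ident, lut))
  set.seed(3); a <- apply_random_lut(two)
  set.seed(3); b <- apply_random_lut(two)
  expect_identical(a, b)
  expect_identical(apply_random_lut(two, randomize = FALSE), two$image)
})

test_that("unit rescaling is the exact linear map with a zero degenerate case", {
  expect_equal(rescale_unit(matrix(c(10, 20, 30), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(rescale_unit(matrix(7, 3, 3)), matrix(0, 3, 3))
  set.seed(4)
  r <- rescale_unit(matrix(rnorm(100), 10, 10))
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)
})

test_that("centred crops land the lesion center at the crop center pixel", {
  cfg <- augmentation_config(crop_size = 32, max_perturb = 7)
  img <- matrix(runif(96 * 96), 96, 96)
  mask <- matrix(0L, 96, 96)
  center <- c(40, 57)
  img[center[1] + 1, center[2] + 1] <- 2   # sentinel at the 0-based center
  mask[center[1] + 1, center[2] + 1] <- 1L
  cr <- crop_lesion(img, mask, center, cfg, train_mode = FALSE)
  expect_identical(dim(cr$image), c(32L, 32L))
  expect_equal(cr$image[17, 17], 2)        # 0-based (16, 16) = crop_size/2
  expect_equal(cr$mask[17, 17], 1L)
})

test_that("crops keep their shape and contain the center for any geometry", {
  cfg <- augmentation_config(crop_size = 16, max_perturb = 7)
  img <- matrix(runif(24 * 24), 24, 24)
  mask <- matrix(0L, 24, 24)
  corners <- list(c(0, 0), c(0, 23), c(23, 0), c(23, 23), c(11, 11))
  for (center in corners) {
    sent <- img[center[1] + 1, center[2] + 1]
    for (rep in 1:25) {                     # exhaust the perturbation draws
      cr <- crop_lesion(img, mask, center, cfg, train_mode = TRUE)
      expect_identical(dim(cr$image), c(16L, 16L))
      # |delta| <= 7 < 8 guarantees the lesion center is inside the crop
      expect_true(sent %in% cr$image)
    }
  }
})

test_that("horizontal flip is an involution applied to both arrays", {
  img <- matrix(runif(36), 6, 6); mask <- matrix(rbinom(36, 1, .5), 6, 6)
  f1 <- hflip(img, mask)
  f2 <- hflip(f1$image, f1$mask)
  expect_identical(f2$image, img)
  expect_identical(f2$mask, mask)
  set.seed(5)
  r <- random_hflip(img, mask, p = 0)
  expect_identical(r$image, img)
  expect_false(r$flipped)
})

test_that("flip frequency matches p = 0.5 over 10000 seeded draws", {
  img <- matrix(1:4 + 0, 2, 2); mask <- matrix(0L, 2, 2)
  set.seed(6)
  flips <- replicate(10000, random_hflip(img, mask, 0.5)$flipped)
  expect_gte(mean(flips), 0.48)
  expect_lte(mean(flips), 0.52)
})

test_that("gamma transform fixes endpoints and preserves ordering", {
  img <- matrix(runif(64), 8, 8); img[1] <- 0; img[64] <- 1
  set.seed(7)
  out <- random_gamma(img, c(0.95, 1.05))
  expect_equal(out[1], 0)
  expect_equal(out[64], 1)
  expect_identical(order(out), order(img))
  expect_identical(random_gamma(img, c(1, 1)), img)
})

test_that("noise magnitude follows the drawn sigma and clips to [0, 1]", {
  img <- matrix(0.5, 1000, 1000)
  expect_identical(add_gaussian_noise(img, 0), img)
  set.seed(8); out <- add_gaussian_noise(img, 0.05)
  set.seed(8); sigma <- runif(1, 0, 0.05)   # replay the drawn magnitude
  expect_lt(abs(sd(out - img) - sigma) / sigma, 0.05)
  expect_true(all(out >= 0 & out <= 1))
  set.seed(9)
  spiky <- add_gaussian_noise(matrix(c(0, 1), 64, 64), 0.9)
  expect_true(all(spiky >= 0 & spiky <= 1))
})

test_that("full pipeline is congruent, bounded, and reproducible", {
  cfg <- augmentation_config(crop_size = 32, max_perturb = 7)
  s <- make_sample(64, seed = 10)
  mask <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
  set.seed(11); t1 <- train_transform(s, mask, cfg)
  set.seed(11); t2 <- train_transform(s, mask, cfg)
  set.seed(12); t3 <- train_transform(s, mask, cfg)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_identical(dim(t1$image), c(32L, 32L))
  expect_identical(dim(t1$mask), c(32L, 32L))
  expect_true(all(t1$image >= 0 & t1$image <= 1))
  expect_true(all(t1$mask %in% c(0L, 1L)))
})

test_that("the evaluation transform is deterministic and idempotent", {
  cfg <- augmentation_config(crop_size = 32, max_perturb = 7)
  s <- make_sample(64, seed = 13)
  mask <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
  e1 <- eval_transform(s, mask, cfg)
  e2 <- eval_transform(s, mask, cfg)
  expect_identical(e1, e2)
  # feeding its own output back (center at the crop center) is the identity
  s2 <- mammogram_sample(e1$image, "P1", "CC", "L", c(16, 16),
                         degenerate = TRUE)
  e3 <- eval_transform(s2, e1$mask, cfg)
  expect_equal(e3$image, rescale_unit(e1$image))
  expect_identical(e3$mask, e1$mask)
})
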