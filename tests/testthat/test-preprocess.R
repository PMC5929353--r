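# Image conditioning: correction, binning, cropping, augmentation, global
# and local contrast normalization, linear-contrast comparator.

test_that("correct_frame subtracts dark and applies gain on trusted pixels", {
  mask <- matrix(TRUE, 4, 4); mask[1, 1] <- FALSE
  raw <- detector_frame(matrix(10, 4, 4), mask = mask)
  dark <- matrix(10, 4, 4)
  expect_true(all(correct_frame(raw, dark)$pixels == 0))

  gain <- matrix(1, 4, 4); gain[2, 2] <- 7
  raw2 <- detector_frame(matrix(13, 4, 4), mask = mask)
  out <- correct_frame(raw2, dark, gain)
  expect_identical(out$pixels[2, 2], 21)   # (13 - 10) * 7
  expect_identical(out$pixels[3, 3], 3)
  expect_identical(out$pixels[1, 1], 0)    # untrusted stays 0

  expect_identical(correct_frame(raw)$pixels, raw$pixels)  # no-op
  expect_error(correct_frame(raw, matrix(0, 3, 3)), "shape")
  # negative results are preserved
  neg <- correct_frame(detector_frame(matrix(5, 4, 4), mask = mask),
                       matrix(8, 4, 4))
  expect_identical(neg$pixels[2, 2], -3)
})

test_that("bin_image sums blocks and matches the naive oracle", {
  expect_identical(bin_image(matrix(1, 8, 8), 4), matrix(16, 2, 2))
  m <- matrix(rnorm(49), 7, 7)
  expect_identical(bin_image(m, 1), m)
  ramp <- matrix(seq_len(81), 9, 9)
  expect_equal(bin_image(ramp, 4), naive_bin(ramp, 4))
  # sum conservation up to trimmed rows/cols
  expect_equal(sum(bin_image(ramp, 4)), sum(ramp[1:8, 1:8]))
  # oracle equivalence on random inputs
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:12, 1); f <- sample(2:3, 1)
    x <- matrix(rnorm(n * n), n, n)
    expect_equal(bin_image(x, f), naive_bin(x, f), tolerance = 1e-12)
  }
  expect_error(bin_image(m, 0), "integer >= 1")
})

test_that("crop_image follows the window convention and never reads outside", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  cr <- crop_image(img, c(50, 50), 10)
  expect_identical(attr(cr, "origin"), c(45, 45))
  expect_identical(cr[1, 1], img[45, 45])
  expect_identical(dim(cr), c(10L, 10L))

  # size = full edge with centered beam -> identity
  full <- crop_image(img, c(50.5, 50.5), 100)
  expect_identical(full[, ], img)

  # random mode with zero shift equals center mode
  set.seed(3)
  expect_identical(crop_image(img, c(50, 50), 10, mode = "random",
                              max_shift = 0)[, ],
                   cr[, ])
  # clamping keeps the window inside the image for any shift
  set.seed(4)
  for (i in 1:20) {
    cc <- crop_image(img, c(3, 97), 10, mode = "random", max_shift = 8)
    org <- attr(cc, "origin")
    expect_true(all(org >= 1) && all(org + 10 - 1 <= 100))
  }
  expect_error(crop_image(img, c(50, 50), 101), "larger than image")
})

test_that("augment_image degenerate settings are the identity", {
  img <- matrix(rnorm(64), 8, 8)
  set.seed(1)
  expect_identical(augment_image(img, flips = FALSE, max_shift = 0,
                                 scale_range = c(1, 1)), img)
  set.seed(2)
  expect_equal(augment_image(img, flips = FALSE, max_shift = 0,
                             scale_range = c(2, 2)), 2 * img)
  # flipping twice restores the image
  flip_h <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(flip_h(flip_h(img)), img)
  # deterministic given the RNG state
  set.seed(9); a <- augment_image(img, max_shift = 2)
  set.seed(9); b <- augment_image(img, max_shift = 2)
  expect_identical(a, b)
  expect_error(augment_image(img, scale_range = c(0, 1)), "positive")
})

test_that("global_normalize standardizes with population sigma", {
  g <- global_normalize(matrix(1:4, 2, 2, byrow = TRUE))
  # mean 2.5, population sd sqrt(1.25)
  expect_equal(g$stats$mu, 2.5)
  expect_equal(g$stats$sigma, sqrt(1.25))
  expect_equal(g$image, (matrix(1:4, 2, 2, byrow = TRUE) - 2.5) / sqrt(1.25),
               tolerance = 1e-12)
  # output has mean 0, sd 1 over trusted pixels; idempotent within 1e-6
  set.seed(5)
  x <- matrix(rnorm(400, 7, 3), 20, 20)
  mask <- matrix(runif(400) > 0.1, 20, 20)
  out <- global_normalize(x, mask)$image
  expect_lt(abs(mean(out[mask])), 1e-9)
  expect_equal(sqrt(mean(out[mask]^2)), 1, tolerance = 1e-9)
  again <- global_normalize(out, mask)$image
  expect_equal(again, out, tolerance = 1e-6)
  expect_error(global_normalize(matrix(3, 4, 4)), "zero variance")
  # oracle equivalence
  for (i in 1:5) {
    y <- matrix(rnorm(100), 10, 10)
    expect_equal(global_normalize(y)$image, naive_global_norm(y),
                 tolerance = 1e-9)
  }
})

test_that("local_contrast_normalize matches the brute-force oracle", {
  set.seed(8)
  for (i in 1:10) {
    x <- matrix(rnorm(49), 7, 7)
    expect_equal(local_contrast_normalize(x, params = lcn_params(3)),
                 naive_lcn(x, window = 3), tolerance = 1e-9)
  }
  # with an untrusted region excluded from the statistics
  x <- matrix(rnorm(81), 9, 9)
  mask <- matrix(TRUE, 9, 9); mask[4:6, 4:5] <- FALSE
  expect_equal(local_contrast_normalize(x, mask, lcn_params(3)),
               naive_lcn(x, mask, window = 3), tolerance = 1e-9)
  # locally constant region -> 0 (sigma floored by epsilon)
  flat <- matrix(0, 9, 9); flat[1, 9] <- 5; flat[9, 1] <- -5
  out <- local_contrast_normalize(flat, params = lcn_params(3))
  expect_identical(out[5, 5], 0)
  expect_error(local_contrast_normalize(matrix(0, 4, 4),
                                        params = lcn_params(5)),
               "window larger")
  expect_error(lcn_params(4), "odd")
})

test_that("the global+local pipeline is affine invariant", {
  set.seed(10)
  x <- matrix(rnorm(30 * 30, 50, 12), 30, 30)
  base <- local_contrast_normalize(global_normalize(x)$image)
  for (a in c(0.5, 3)) {
    for (b in c(-10, 100)) {
      y <- a * x + b
      out <- local_contrast_normalize(global_normalize(y)$image)
      expect_equal(out, base, tolerance = 1e-6)
    }
  }
})

test_that("linear_contrast implements the display transform", {
  img <- matrix(c(0, 1, 2, 10), 2, 2)
  p90 <- as.numeric(quantile(img, 0.9, names = FALSE))
  out <- linear_contrast(img, M = 1)
  expect_identical(dim(out), dim(img))
  expect_equal(out[2, 2], 1)                       # min(1, .) caps at 1
  expect_equal(out[1, 2], 2 / p90)                 # D = M * P_x / P90
  # P_x = P90: D equals M (the default contrast 0.4); P_x = 0 -> 0
  uniform <- matrix(5, 3, 3)
  expect_true(all(abs(linear_contrast(uniform, M = 0.4) - 0.4) < 1e-12))
  expect_true(all(abs(linear_contrast(uniform, M = 1) - 1) < 1e-12))
  expect_identical(linear_contrast(img, M = 0.4)[1, 1], 0)
  expect_error(linear_contrast(matrix(-1, 3, 3)), "positive")
})

test_that("preprocess_frame wires binning, cropping and contrast together", {
  prof <- flat_profile(c(64L, 64L), psf = 1.2, dark = 20, dark_sigma = 1)
  p <- scene_params(mode = "random", n_spots = 10, background_photons = 4)
  ds <- generate_dataset(1, p, prof, seed = 2)
  f <- ds$stack$frames[[1]]
  out <- preprocess_frame(f, bin = 2, crop_size = 24, contrast = "lcn")
  expect_identical(dim(out), c(24L, 24L))
  lin <- preprocess_frame(f, bin = 2, crop_size = 24, contrast = "linear")
  expect_true(all(lin >= 0 & lin <= 1))
  raw <- preprocess_frame(f, bin = 1, crop_size = NULL, contrast = "none")
  expect_identical(raw, f$pixels)
  # stack preprocessing flattens column-wise and is seed-reproducible
  ds5 <- generate_dataset(5, p, prof, seed = 3)
  pp1 <- preprocess_stack(ds5$stack, bin = 2, crop_size = 24,
                          crop_mode = "random", seed = 11)
  pp2 <- preprocess_stack(ds5$stack, bin = 2, crop_size = 24,
                          crop_mode = "random", seed = 11)
  expect_identical(pp1$inputs, pp2$inputs)
  expect_identical(dim(pp1$inputs), c(24L * 24L, 5L))
})
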