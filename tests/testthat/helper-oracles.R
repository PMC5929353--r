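# Independent naive reference implementations (double loops) used as
# oracles against the vectorized code paths, plus small shared fixtures.

# block-sum binning by explicit double loop
naive_bin <- function(image, f) {
  h <- nrow(image) %/% f
  w <- ncol(image) %/% f
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sum(image[((i - 1) * f + 1):(i * f),
                             ((j - 1) * f + 1):(j * f)])
    }
  }
  out
}

naive_global_norm <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  v <- image[mask]
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / length(v))
  out <- (image - mu) / sigma
  out[!mask] <- 0
  out
}

# LCN by explicit per-pixel window loop with symmetric reflection padding
naive_lcn <- function(image, mask = NULL, window = 3L, epsilon = 1e-4) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  half <- (window - 1) %/% 2
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  v <- image
  v[!mask] <- 0
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!mask[i, j]) next
      vals <- c(); ms <- c()
      for (di in -half:half) {
        for (dj in -half:half) {
          ii <- reflect(i + di, H); jj <- reflect(j + dj, W)
          vals <- c(vals, v[ii, jj]); ms <- c(ms, mask[ii, jj])
        }
      }
      vals <- vals[ms]
      if (length(vals) == 0) next
      mu <- mean(vals)
      sdv <- sqrt(max(mean(vals^2) - mu^2, 0))
      out[i, j] <- (v[i, j] - mu) / max(sdv, epsilon)
    }
  }
  out
}

# zero-padded stride-s convolution of a (possibly multi-channel) input with
# one kernel set, explicit loops; input: H x W x Cin array, W_k: k x k x Cin
naive_conv <- function(input, kernel, stride = 2L) {
  if (length(dim(input)) == 2) input <- array(input, c(dim(input), 1))
  if (length(dim(kernel)) == 2) kernel <- array(kernel, c(dim(kernel), 1))
  k <- dim(kernel)[1]
  pad <- (k - 1) %/% 2
  n <- dim(input)[1]
  cin <- dim(input)[3]
  eo <- ceiling(n / stride)
  padded <- array(0, c(n + 2 * pad, n + 2 * pad, cin))
  padded[pad + seq_len(n), pad + seq_len(n), ] <- input
  out <- matrix(0, eo, eo)
  for (oi in seq_len(eo)) {
    for (oj in seq_len(eo)) {
      r0 <- stride * (oi - 1)
      c0 <- stride * (oj - 1)
      acc <- 0
      for (c in seq_len(cin)) {
        acc <- acc + sum(padded[r0 + seq_len(k), c0 + seq_len(k), c] *
                           kernel[, , c])
      }
      out[oi, oj] <- acc
    }
  }
  out
}

naive_maxpool <- function(image, p = 2L) {
  e <- nrow(image) %/% p
  out <- matrix(0, e, e)
  for (i in seq_len(e)) {
    for (j in seq_len(e)) {
      out[i, j] <- max(image[((i - 1) * p + 1):(i * p),
                             ((j - 1) * p + 1):(j * p)])
    }
  }
  out
}

# small shared fixtures -----------------------------------------------------

quick_arch <- function(input = 48L, channels = c(2L, 4L, 8L)) {
  cnn_architecture(input_size = input, channels = channels)
}

flat_profile <- function(shape = c(64L, 64L), psf = 1, dark = 0,
                         dark_sigma = 0) {
  detector_profile("flat_synth", shape, psf_sigma = psf, dark_mean = dark,
                   dark_sigma = dark_sigma, saturation_level = 1e6)
}

random_annotations <- function(n, labels = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(labels)) {
    labels <- sample(c("Hit", "Maybe", "Miss"), n, replace = TRUE)
  }
  annotation_table(sprintf("f%04d", seq_len(n)), labels)
}

# tiny, quickly separable dataset: bright multi-spot frames vs blanks vs
# intermediates, flat small detector
easy_dataset <- function(n, seed = 1) {
  prof <- flat_profile(c(48L, 48L), psf = 1.2, dark = 10, dark_sigma = 1)
  mk <- function(nsp) scene_params(mode = "random", n_spots = nsp,
                                   spot_intensity = c(median = 150,
                                                      spread = 0.2),
                                   b_factor = 0.5, background_photons = 3)
  mix <- scene_mixture(list(mk(16), mk(6.5), mk(0.2)), c(0.4, 0.25, 0.35))
  generate_dataset(n, mix, prof, seed = seed)
}
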