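# Image conditioning: correction, photon-preserving binning, cropping and
# augmentation, global normalization, local contrast normalization (LCN),
# and the linear-contrast comparator used by the preprocessing ablation.
#
# Conventions: (row, col) coordinates, 1-based in R; untrusted pixels are
# carried as zeros through convolutional stages but are excluded from all
# normalization statistics (global and local).

#' LCN parameters
#'
#' @param window odd integer edge length (>= 3) of the square neighborhood
#'   over which the local mean and standard deviation are taken. The
#'   neighborhood size is not dictated by the method itself; the default 9
#'   spans a large-point-spread spot plus margin at 4x4-binned scale.
#' @param epsilon small positive floor for the local standard deviation,
#'   preventing division blow-ups in flat regions.
#' @return an object of class `lcn_params`.
#' @export
lcn_params <- function(window = 9L, epsilon = 1e-4) {
  window <- as.integer(window)
  abort_if(window < 3 || window %% 2 == 0, "window must be odd and >= 3")
  abort_if(!(epsilon > 0), "epsilon must be > 0")
  structure(list(window = window, epsilon = epsilon), class = "lcn_params")
}

#' Dark subtraction and gain scaling
#'
#' `pixels = (raw - dark) * gain_map` on trusted pixels; untrusted pixels
#' remain 0. Negative results are preserved (dark subtraction can produce a
#' few negative pixels; this does not harm downstream classification).
#'
#' @param raw a [detector_frame()].
#' @param dark optional [detector_frame()] (or matrix) of average dark
#'   current, same shape.
#' @param gain_map optional numeric matrix of per-pixel gain factors (for
#'   example about 7 for low-gain pixels, to place gain zones on one scale).
#' @return a corrected [detector_frame()].
#' @export
correct_frame <- function(raw, dark = NULL, gain_map = NULL) {
  abort_if(!inherits(raw, "detector_frame"), "raw must be a detector_frame")
  px <- raw$pixels
  if (!is.null(dark)) {
    dk <- if (inherits(dark, "detector_frame")) dark$pixels else dark
    abort_if(!identical(dim(dk), dim(px)), "dark shape mismatch")
    px <- px - dk
  }
  if (!is.null(gain_map)) {
    abort_if(!identical(dim(gain_map), dim(px)), "gain_map shape mismatch")
    px <- px * gain_map
  }
  px[!raw$mask] <- 0
  out <- raw
  out$pixels <- px
  out
}

#' Photon-preserving image binning
#'
#' Each output pixel is the SUM of its `factor x factor` block, so total
#' intensity (photon counts) is conserved up to edge rows/columns trimmed
#' from the high end when the shape is not divisible by `factor`. Summing
#' rather than averaging differs only by a global scale, which the
#' subsequent global normalization absorbs.
#'
#' @param image numeric matrix.
#' @param factor integer >= 1 (4 is the usual downsampling for training).
#' @return matrix of shape `floor(dim(image) / factor)`.
#' @export
bin_image <- function(image, factor) {
  abort_if(!is_count(factor) || factor < 1, "factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- nrow(image) %/% factor
  w <- ncol(image) %/% factor
  abort_if(h < 1 || w < 1, "factor larger than image")
  x <- image[seq_len(h * factor), seq_len(w * factor), drop = FALSE]
  y <- rowsum(x, rep(seq_len(h), each = factor))
  out <- t(rowsum(t(y), rep(seq_len(w), each = factor)))
  dimnames(out) <- NULL
  out
}

# Binned trust mask: a binned pixel is trusted iff every pixel in its block
# is trusted.
#' @noRd
bin_mask <- function(mask, factor) {
  if (factor == 1L) return(mask)
  bin_image(matrix(as.numeric(mask), nrow(mask), ncol(mask)), factor) ==
    factor^2
}

#' Crop a square window around the beam center
#'
#' `center` mode extracts a `size x size` window centered at `beam_center`;
#' `random` mode first offsets the window center by independent integer
#' shifts uniform on `[-max_shift, max_shift]` per axis (the augmentation
#' used to generate translated training images). The window is clamped to
#' the image boundary, so no out-of-image pixels are ever read; `random`
#' mode with `max_shift = 0` equals `center` mode.
#'
#' @param image numeric matrix.
#' @param beam_center `(row, col)`, 1-based.
#' @param size output edge length (<= both image edges).
#' @param mode `"center"` or `"random"`.
#' @param max_shift maximum absolute shift per axis for random mode.
#' @return `size x size` matrix with attribute `origin` = 1-based
#'   `(row, col)` of the window's top-left pixel in the input.
#' @export
crop_image <- function(image, beam_center, size,
                       mode = c("center", "random"), max_shift = 5L) {
  mode <- match.arg(mode)
  abort_if(size > nrow(image) || size > ncol(image),
           "crop size larger than image")
  ctr <- round(beam_center)
  if (mode == "random" && max_shift > 0) {
    ctr <- ctr + c(sample(-max_shift:max_shift, 1),
                   sample(-max_shift:max_shift, 1))
  }
  start <- ctr - floor(size / 2)
  start[1] <- min(max(start[1], 1), nrow(image) - size + 1)
  start[2] <- min(max(start[2], 1), ncol(image) - size + 1)
  out <- image[start[1]:(start[1] + size - 1),
               start[2]:(start[2] + size - 1), drop = FALSE]
  attr(out, "origin") <- start
  out
}

#' Stochastic training augmentation
#'
#' Applies, in order: optional horizontal/vertical flips (each with
#' probability 0.5), a random integer translation (zero-filled) with per-axis
#' shifts uniform on `[-max_shift, max_shift]`, and a multiplicative
#' intensity scale drawn uniformly from `scale_range`. Rotation by multiples
#' of 90 degrees is available but disabled by default (free-rotation angles
#' are not part of the augmentation set).
#'
#' @param image numeric matrix.
#' @param flips enable random flips.
#' @param max_shift maximum absolute translation per axis (pixels).
#' @param scale_range length-2 positive range for the intensity scale.
#' @param rotate90 if `TRUE`, also rotate by a random multiple of 90
#'   degrees.
#' @return augmented matrix, same shape.
#' @export
augment_image <- function(image, flips = TRUE, max_shift = 0L,
                          scale_range = c(1, 1), rotate90 = FALSE) {
  abort_if(any(scale_range <= 0), "scale_range must be positive")
  out <- image
  if (flips) {
    if (runif(1) < 0.5) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
    if (runif(1) < 0.5) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  if (max_shift > 0) {
    dr <- sample(-max_shift:max_shift, 1)
    dc <- sample(-max_shift:max_shift, 1)
    shifted <- matrix(0, nrow(out), ncol(out))
    src_r <- seq_len(nrow(out)) - dr
    src_c <- seq_len(ncol(out)) - dc
    ok_r <- src_r >= 1 & src_r <= nrow(out)
    ok_c <- src_c >= 1 & src_c <= ncol(out)
    shifted[which(ok_r), which(ok_c)] <- out[src_r[ok_r], src_c[ok_c]]
    out <- shifted
  }
  if (rotate90) {
    k <- sample(0:3, 1)
    for (i in seq_len(k)) out <- t(out[rev(seq_len(nrow(out))), ,
                                       drop = FALSE])
  }
  if (!(scale_range[1] == 1 && scale_range[2] == 1)) {
    out <- out * runif(1, scale_range[1], scale_range[2])
  }
  out
}

#' Global normalization
#'
#' Standardizes the image to zero mean and unit (population) standard
#' deviation, `v(x) = (x - mu) / sigma`, where `mu` and `sigma` are taken
#' over the trusted pixels of the entire image. Untrusted pixels are set to
#' 0 in the output.
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix (`TRUE` = trusted); default all.
#' @return list with `image` (normalized matrix) and `stats`
#'   (`mu`, `sigma`).
#' @export
global_normalize <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  vals <- image[mask]
  abort_if(length(vals) < 2, "need at least two trusted pixels")
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  abort_if(sigma == 0, "degenerate input: zero variance over trusted pixels")
  out <- (image - mu) / sigma
  out[!mask] <- 0
  list(image = out, stats = list(mu = mu, sigma = sigma))
}

# Window sums of `padded` (already padded by `half` on every side) for every
# interior pixel, via a summed-area table.
#' @noRd
box_sums <- function(padded, half, H, W) {
  s <- apply(padded, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- cbind(0, rbind(0, s))
  w <- 2 * half + 1
  r1 <- seq_len(H); c1 <- seq_len(W)
  s[r1 + w, c1 + w, drop = FALSE] - s[r1, c1 + w, drop = FALSE] -
    s[r1 + w, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

#' @noRd
reflect_pad <- function(m, half) {
  ri <- c(rev(seq_len(half)), seq_len(nrow(m)),
          nrow(m) - seq_len(half) + 1)
  ci <- c(rev(seq_len(half)), seq_len(ncol(m)),
          ncol(m) - seq_len(half) + 1)
  m[ri, ci, drop = FALSE]
}

#' Local contrast normalization
#'
#' Per-pixel standardization by the neighborhood mean and standard
#' deviation: `out(x) = (v(x) - mu_N(x)) / max(sigma_N(x), epsilon)`, where
#' the statistics are taken over the `window x window` neighborhood of `x`
#' restricted to trusted pixels, and `v` is the globally normalized image.
#' Boundary windows use reflection padding. LCN flattens background
#' variation and enhances the contrast between background and Bragg spots,
#' which is what makes network training tractable on raw detector data.
#'
#' The input is expected to be globally normalized already; compose with
#' [global_normalize()] (as [preprocess_frame()] does) when starting from a
#' raw frame. Because global normalization removes affine intensity maps,
#' the composed pipeline satisfies `LCN(a * x + b) = LCN(x)` for `a > 0`.
#'
#' @param image numeric matrix (globally normalized).
#' @param mask optional logical trust mask.
#' @param params an [lcn_params()].
#' @return normalized matrix; untrusted pixels and pixels with no trusted
#'   neighbor are 0.
#' @export
local_contrast_normalize <- function(image, mask = NULL,
                                     params = lcn_params()) {
  abort_if(!inherits(params, "lcn_params"), "params must be lcn_params")
  H <- nrow(image); W <- ncol(image)
  abort_if(params$window > H || params$window > W,
           "window larger than image")
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  half <- (params$window - 1L) %/% 2L
  v <- image
  v[!mask] <- 0
  mpad <- reflect_pad(matrix(as.numeric(mask), H, W), half)
  vpad <- reflect_pad(v, half)
  cnt <- box_sums(mpad, half, H, W)
  s1 <- box_sums(vpad * mpad, half, H, W)
  s2 <- box_sums(vpad^2 * mpad, half, H, W)
  safe <- pmax(cnt, 1)
  mu <- s1 / safe
  varr <- pmax(s2 / safe - mu^2, 0)
  out <- (v - mu) / pmax(sqrt(varr), params$epsilon)
  out[cnt == 0 | !mask] <- 0
  out
}

#' Linear-contrast display transform
#'
#' The simple per-pixel display scaling used by diffraction image viewers:
#' `D = min(1, M * P_x / P90)`, where `P90` is the image's 90th-percentile
#' pixel value and `M` is a contrast parameter (range about 0.004 to 2,
#' default 0.4). Values are additionally floored at 0. Serves as the
#' comparator against LCN in the preprocessing ablation.
#'
#' @param image numeric matrix with a positive 90th percentile.
#' @param M contrast parameter.
#' @return matrix with values in `[0, 1]`.
#' @export
linear_contrast <- function(image, M = 0.4) {
  p90 <- as.numeric(quantile(image, 0.9, names = FALSE))
  abort_if(!(p90 > 0), "degenerate input: 90th percentile must be positive")
  out <- pmin(1, pmax(0, M * image / p90))  # pmin drops dim attributes
  matrix(out, nrow(image), ncol(image))
}

#' Condition one frame for classification
#'
#' The standard pipeline: bin by `bin` (photon-preserving sums), crop a
#' `crop_size` window about the (binned) beam center, then apply the chosen
#' contrast stage: `"lcn"` = global normalization followed by local contrast
#' normalization, `"linear"` = the display-style linear contrast transform,
#' `"none"` = raw cropped intensities.
#'
#' @param frame a [detector_frame()].
#' @param bin integer binning factor.
#' @param crop_size output edge length; `NULL` skips cropping.
#' @param crop_mode `"center"` or `"random"` (random adds the translation
#'   augmentation before cropping).
#' @param max_shift maximum shift for random cropping.
#' @param contrast `"lcn"`, `"linear"` or `"none"`.
#' @param lcn an [lcn_params()].
#' @param M linear-contrast parameter.
#' @param include_masked if `TRUE`, untrusted pixels participate in the
#'   normalization statistics as zeros (the literal behavior of running the
#'   normalization on a monolithic zero-filled array); by default they are
#'   excluded to keep the statistics stable.
#' @return numeric matrix ready for the classifier input.
#' @export
preprocess_frame <- function(frame, bin = 4L, crop_size = NULL,
                             crop_mode = c("center", "random"),
                             max_shift = 5L,
                             contrast = c("lcn", "linear", "none"),
                             lcn = lcn_params(), M = 0.4,
                             include_masked = FALSE) {
  abort_if(!inherits(frame, "detector_frame"),
           "frame must be a detector_frame")
  crop_mode <- match.arg(crop_mode)
  contrast <- match.arg(contrast)
  img <- bin_image(frame$pixels, bin)
  msk <- bin_mask(frame$mask, bin)
  bc <- (frame$beam_center - 1) / bin + 1
  if (!is.null(crop_size)) {
    img <- crop_image(img, bc, crop_size, mode = crop_mode,
                      max_shift = max_shift)
    org <- attr(img, "origin")
    msk <- msk[org[1]:(org[1] + crop_size - 1),
               org[2]:(org[2] + crop_size - 1), drop = FALSE]
  }
  if (include_masked) msk <- matrix(TRUE, nrow(img), ncol(img))
  switch(contrast,
         lcn = {
           g <- global_normalize(img, msk)
           local_contrast_normalize(g$image, msk, lcn)
         },
         linear = linear_contrast(img, M),
         none = img)
}

#' Condition a whole stack
#'
#' Applies [preprocess_frame()] to every frame and flattens the results into
#' the `(pixels, frames)` input matrix consumed by the classifier.
#'
#' @param stack a [frame_stack()].
#' @inheritParams preprocess_frame
#' @param seed optional seed making random cropping reproducible.
#' @return list with `inputs` (matrix, one column per frame, pixels in
#'   column-major order), `frame_ids`, and `edge` (image edge length).
#' @export
preprocess_stack <- function(stack, bin = 4L, crop_size = NULL,
                             crop_mode = "center", max_shift = 5L,
                             contrast = "lcn", lcn = lcn_params(), M = 0.4,
                             include_masked = FALSE, seed = NULL) {
  abort_if(!inherits(stack, "frame_stack"), "stack must be a frame_stack")
  run <- function() {
    mats <- lapply(stack$frames, preprocess_frame, bin = bin,
                   crop_size = crop_size, crop_mode = crop_mode,
                   max_shift = max_shift, contrast = contrast, lcn = lcn,
                   M = M, include_masked = include_masked)
    edge <- nrow(mats[[1]])
    abort_if(edge != ncol(mats[[1]]),
             "classifier input must be square; choose a crop_size")
    inputs <- vapply(mats, as.numeric, numeric(edge * ncol(mats[[1]])))
    list(inputs = matrix(inputs, ncol = length(mats)),
         frame_ids = stack_ids(stack), edge = edge)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
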