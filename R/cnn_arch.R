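# Network architecture: a stack of convolution / batch-norm / ReLU /
# max-pool filter stages followed by one fully connected layer and SoftMax
# over (Hit, Maybe, Miss).
#
# Edge rounding convention: a stride-s zero-padded convolution maps edge n
# to ceil(n / s); a p x p max pool maps edge n to floor(n / p). This is the
# unique simple convention under which the default 720-edge input yields
# both the published 8 x 45 x 45 intermediate stack and the 288-long
# flattened feature vector.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Define a CNN architecture
#'
#' @param input_size square input edge in pixels. The default 720 is the
#'   4x4-binned, center-cropped training size for which the default stages
#'   produce a 288-feature vector.
#' @param kernel_size convolution kernel edge `k` (odd; default 3).
#' @param stride convolution stride `s` (default 2).
#' @param pool_size max-pool patch edge `p` (default 2).
#' @param channels output channels of each filter stage (default
#'   `c(4, 8, 16, 32)`; the length sets the number of stages).
#' @param n_classes number of output classes (3: Hit, Maybe, Miss).
#' @return an object of class `cnn_architecture` with the derived feature
#'   length `n_features`.
#' @export
cnn_architecture <- function(input_size = 720L, kernel_size = 3L,
                             stride = 2L, pool_size = 2L,
                             channels = c(4L, 8L, 16L, 32L),
                             n_classes = 3L) {
  abort_if(kernel_size %% 2 == 0, "kernel_size must be odd")
  arch <- structure(list(input_size = as.integer(input_size),
                         kernel_size = as.integer(kernel_size),
                         stride = as.integer(stride),
                         pool_size = as.integer(pool_size),
                         channels = as.integer(channels),
                         n_classes = as.integer(n_classes)),
                    class = "cnn_architecture")
  chain <- shape_chain(arch)  # validates that no stage collapses to zero
  arch$n_features <- attr(chain, "n_features")
  arch
}

#' Per-stage shape chain of a CNN architecture
#'
#' Propagates the square edge length through every filter stage: the
#' convolution edge is `ceil(edge / stride)` (zero-padded) and the pooled
#' edge is `floor(conv_edge / pool_size)`. The flattened feature length is
#' the final channel count times the final edge squared; with the default
#' architecture, 720 -> (4, 180) -> (8, 45) -> (16, 11) -> (32, 3) and the
#' feature length is 32 x 3 x 3 = 288.
#'
#' @param arch a [cnn_architecture()] (or a bare list with the same
#'   fields).
#' @return data.frame with columns `stage`, `channels`, `conv_edge`,
#'   `pool_edge`; attribute `n_features` holds the flattened length.
#' @export
shape_chain <- function(arch) {
  edge <- arch$input_size
  out <- data.frame(stage = seq_along(arch$channels),
                    channels = arch$channels, conv_edge = NA_integer_,
                    pool_edge = NA_integer_)
  for (i in seq_along(arch$channels)) {
    conv <- ceiling(edge / arch$stride)
    pool <- conv %/% arch$pool_size
    abort_if(pool < 1,
             "architecture error: stage %d output collapses to zero (edge %d)",
             i, edge)
    out$conv_edge[i] <- as.integer(conv)
    out$pool_edge[i] <- as.integer(pool)
    edge <- as.integer(pool)
  }
  attr(out, "n_features") <- as.integer(tail(arch$channels, 1) * edge^2)
  out
}

#' Initialize network weights
#'
#' Variance-scaled symmetric (He-style) random initialization for the
#' convolution kernels and the fully connected layer; batch-norm scale 1,
#' shift 0, running statistics (0, 1). Deterministic given `seed`.
#'
#' @param arch a [cnn_architecture()].
#' @param seed integer seed.
#' @return an object of class `cnn_weights` (carries the architecture).
#' @export
init_weights <- function(arch, seed = 1L) {
  abort_if(!inherits(arch, "cnn_architecture"),
           "arch must be a cnn_architecture")
  with_seed(seed, {
    k2 <- arch$kernel_size^2
    cin <- c(1L, head(arch$channels, -1))
    stages <- lapply(seq_along(arch$channels), function(i) {
      fan_in <- k2 * cin[i]
      cout <- arch$channels[i]
      list(W = matrix(rnorm(cout * k2 * cin[i], 0, sqrt(2 / fan_in)),
                      cout, k2 * cin[i]),
           gamma = rep(1, cout), beta = rep(0, cout),
           run_mean = rep(0, cout), run_var = rep(1, cout))
    })
    fc <- list(W = matrix(rnorm(arch$n_classes * arch$n_features, 0,
                                sqrt(1 / arch$n_features)),
                          arch$n_classes, arch$n_features),
               b = rep(0, arch$n_classes))
    structure(list(stages = stages, fc = fc, arch = arch),
              class = "cnn_weights")
  })
}

#' Save / load network weights
#'
#' Versioned binary container with the architecture record embedded.
#'
#' @param weights a `cnn_weights` object.
#' @param path file path.
#' @return [load_weights()] returns the `cnn_weights` object.
#' @export
save_weights <- function(weights, path) {
  abort_if(!inherits(weights, "cnn_weights"),
           "weights must be a cnn_weights object")
  saveRDS(list(format = "braggscreen_cnn", version = 1L, weights = weights),
          path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- readRDS(path)
  abort_if(!identical(obj$format, "braggscreen_cnn"),
           "'%s' is not a braggscreen weight container", path)
  obj$weights
}

# ---- execution plan -------------------------------------------------------
# Per-architecture cache of the index maps used by the vectorized forward
# and backward passes (im2col gather indices, padding interiors, pool corner
# selectors).

.plan_cache <- new.env(parent = emptyenv())

#' @noRd
build_plan <- function(arch) {
  key <- paste(arch$input_size, arch$kernel_size, arch$stride,
               arch$pool_size, paste(arch$channels, collapse = "."),
               sep = "|")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  chain <- shape_chain(arch)
  k <- arch$kernel_size; s <- arch$stride; p <- arch$pool_size
  pad <- (k - 1L) %/% 2L
  cin <- c(1L, head(arch$channels, -1))
  edges_in <- c(arch$input_size, head(chain$pool_edge, -1))
  stages <- vector("list", length(arch$channels))
  for (i in seq_along(arch$channels)) {
    n <- edges_in[i]; Cin <- cin[i]
    np <- n + 2L * pad
    Eo <- chain$conv_edge[i]; Ep <- chain$pool_edge[i]
    starts <- s * (0:(Eo - 1L))           # 0-based start in padded grid
    Mi <- outer(1:k, starts, "+")         # padded row index (dr, oi)
    Mj <- outer(1:k, starts, "+")
    idx_dr <- rep(1:k, times = k * Cin)
    idx_dc <- rep(rep(1:k, each = k), times = Cin)
    idx_oi <- rep(1:Eo, times = Eo)
    idx_oj <- rep(1:Eo, each = Eo)
    i_full <- Mi[idx_dr, idx_oi, drop = FALSE]
    j_full <- Mj[idx_dc, idx_oj, drop = FALSE]
    crep <- rep(1:Cin, each = k * k)
    IDX <- i_full + np * (j_full - 1L) + np^2 * (crep - 1L)
    IDX <- as.integer(IDX)
    interior <- as.integer(
      rep(1:n, times = n * Cin) + pad +
        np * (rep(rep(1:n, each = n), times = Cin) + pad - 1L) +
        np^2 * (rep(1:Cin, each = n^2) - 1L))
    # pool corner selectors over the Eo x Eo conv-out spatial grid
    pi0 <- rep(0:(Ep - 1L), times = Ep)
    pj0 <- rep(0:(Ep - 1L), each = Ep)
    corners <- vector("list", p * p)
    for (dj in 0:(p - 1L)) for (di in 0:(p - 1L)) {
      corners[[di + p * dj + 1L]] <-
        as.integer((p * pi0 + di + 1L) + Eo * (p * pj0 + dj))
    }
    stages[[i]] <- list(n = n, Cin = Cin, Cout = arch$channels[i], np = np,
                        Lpad = np^2 * Cin, Eo = Eo, Ep = Ep, IDX = IDX,
                        u_idx = sort(unique(IDX)), interior = interior,
                        corners = corners, k2cin = k * k * Cin)
  }
  plan <- list(stages = stages, n_features = attr(chain, "n_features"))
  .plan_cache[[key]] <- plan
  plan
}
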