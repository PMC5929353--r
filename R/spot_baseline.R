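# Simplified threshold spotfinder + count-threshold hit classifier.
#
# A pixel is "strong" iff it is trusted AND exceeds the global threshold AND
# its excess over the local background mean is significant: value -
# local_mean > sigma_strong * max(local_sd, sqrt(gain * max(local_mean, 0))).
# Local statistics are taken over a square window excluding the pixel itself
# and excluding untrusted pixels. Strong pixels are grouped by
# 4-connectivity; groups meeting the minimum area become spot candidates.
# This is a deliberate simplification of production dispersion-style
# spotfinders: the package uses it only as a comparator against ground
# truth, not as a re-implementation of any particular toolbox.

#' Spotfinder parameters
#'
#' @param gain detector gain in ADU per photon (used in the Poisson term of
#'   the significance test).
#' @param global_threshold minimum ADU value for a strong pixel.
#' @param sigma_strong significance multiple for the local test.
#' @param min_spot_area minimum candidate area in pixels (production
#'   settings are typically 2-3).
#' @param local_window odd window edge for local background statistics.
#' @param count_threshold candidates-per-image count at or above which the
#'   image is classified as a Hit.
#' @return an object of class `spotfinder_params`.
#' @export
spotfinder_params <- function(gain = 1, global_threshold = 50,
                              sigma_strong = 3, min_spot_area = 2,
                              local_window = 7L, count_threshold = 4L) {
  abort_if(gain <= 0 || global_threshold <= 0 || sigma_strong <= 0 ||
             min_spot_area < 1 || count_threshold < 1,
           "spotfinder parameters must be positive")
  local_window <- as.integer(local_window)
  abort_if(local_window < 3 || local_window %% 2 == 0,
           "local_window must be odd and >= 3")
  structure(list(gain = gain, global_threshold = global_threshold,
                 sigma_strong = sigma_strong,
                 min_spot_area = as.integer(min_spot_area),
                 local_window = local_window,
                 count_threshold = as.integer(count_threshold)),
            class = "spotfinder_params")
}

# Union-find with path halving; labels 4-connected components of the
# `strong` pixel set. Returns integer component id per strong pixel.
#' @noRd
label_components4 <- function(strong_idx, H, W) {
  n <- length(strong_idx)
  if (n == 0) return(integer(0))
  pos <- integer(H * W)
  pos[strong_idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- (strong_idx - 1L) %% H + 1L
  # neighbor down (same column, row + 1) and right (col + 1)
  for (nb_off in c(1L, H)) {
    cand <- strong_idx + nb_off
    ok <- if (nb_off == 1L) rows < H else strong_idx + H <= H * W
    ok <- ok & cand >= 1 & cand <= H * W
    ok[ok] <- pos[cand[ok]] > 0
    a <- pos[strong_idx[ok]]
    b <- pos[cand[ok]]
    for (j in seq_along(a)) {
      ra <- find(a[j]); rb <- find(b[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Find Bragg spot candidates on a frame
#'
#' Applies the strong-pixel test described above and groups strong pixels by
#' 4-connectivity (strict grouping protects 1-pixel spots on
#' small-point-spread detectors from merging). Candidates with area below
#' `min_spot_area` are dropped; the rest are returned sorted by descending
#' peak value. Untrusted pixels can never be members. The frame is expected
#' to be dark-subtracted ([correct_frame()]).
#'
#' @param frame a [detector_frame()].
#' @param params a [spotfinder_params()].
#' @return list of candidates, each with `pixel_members` (matrix of
#'   `(row, col)`), `centroid`, `peak_value`, `area`.
#' @export
find_spots <- function(frame, params) {
  abort_if(!inherits(frame, "detector_frame"),
           "frame must be a detector_frame")
  abort_if(!inherits(params, "spotfinder_params"),
           "params must be spotfinder_params")
  img <- frame$pixels
  msk <- frame$mask
  H <- nrow(img); W <- ncol(img)
  abort_if(params$local_window > H || params$local_window > W,
           "window larger than frame")
  half <- (params$local_window - 1L) %/% 2L

  m <- matrix(as.numeric(msk), H, W)
  v <- img
  v[!msk] <- 0
  # zero padding: out-of-frame pixels contribute like untrusted ones
  zp <- function(x) {
    out <- matrix(0, H + 2 * half, W + 2 * half)
    out[half + seq_len(H), half + seq_len(W)] <- x
    out
  }
  cnt <- box_sums(zp(m), half, H, W) - m          # exclude the center pixel
  s1 <- box_sums(zp(v * m), half, H, W) - v * m
  s2 <- box_sums(zp(v^2 * m), half, H, W) - (v * m)^2
  safe <- pmax(cnt, 1)
  mu <- s1 / safe
  sdv <- sqrt(pmax(s2 / safe - mu^2, 0))
  noise <- pmax(sdv, sqrt(params$gain * pmax(mu, 0)))
  strong <- msk & img > params$global_threshold &
    (img - mu) > params$sigma_strong * noise & cnt > 0

  strong_idx <- which(strong)
  comp <- label_components4(strong_idx, H, W)
  if (length(strong_idx) == 0) return(list())
  groups <- split(strong_idx, comp)
  cands <- lapply(groups, function(ix) {
    if (length(ix) < params$min_spot_area) return(NULL)
    rows <- (ix - 1L) %% H + 1L
    cols <- (ix - 1L) %/% H + 1L
    vals <- img[ix]
    list(pixel_members = cbind(row = rows, col = cols),
         centroid = c(row = sum(rows * vals) / sum(vals),
                      col = sum(cols * vals) / sum(vals)),
         peak_value = max(vals), area = length(ix))
  })
  cands <- Filter(Negate(is.null), cands)
  cands[order(vapply(cands, function(s) s$peak_value, numeric(1)),
              decreasing = TRUE)]
}

#' Count-threshold hit classification
#'
#' Counts spot candidates on a frame and labels it `Hit` iff the count is at
#' least `count_threshold` (non-strict boundary: a count equal to the
#' threshold is retained). The baseline is binary: it has no `Maybe` class.
#'
#' @param frame a [detector_frame()].
#' @param params a [spotfinder_params()].
#' @return list with `count` and `label` (`"Hit"` or `"Miss"`).
#' @export
count_threshold_classify <- function(frame, params) {
  count <- length(find_spots(frame, params))
  list(count = count,
       label = if (count >= params$count_threshold) "Hit" else "Miss")
}

#' Run the baseline over a stack
#'
#' @param stack a [frame_stack()].
#' @param params a [spotfinder_params()].
#' @return data.frame with columns `frame_id`, `count`, `label`.
#' @export
spotfind_stack <- function(stack, params) {
  res <- lapply(stack$frames, count_threshold_classify, params = params)
  data.frame(frame_id = stack_ids(stack),
             count = vapply(res, function(r) r$count, numeric(1)),
             label = vapply(res, function(r) r$label, character(1)),
             stringsAsFactors = FALSE)
}
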