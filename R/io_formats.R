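# Frame-stack and annotation I/O plus deterministic dataset splitting.
#
# HDF5 layout (fixed by this package):
#   /frames    N x H x W int32, /mask H x W uint8 (optional, 1 = trusted),
#   /frame_ids N strings (optional); root attributes beam_center_row,
#   beam_center_col (1-based pixel coordinates), source_tag.

#' Construct a detector frame
#'
#' A detector frame couples one 2-D grid of pixel intensities (arbitrary
#' detector units, ADU) with a validity mask and minimal metadata. Untrusted
#' pixels (mask `FALSE`) are held at value 0 throughout the analysis.
#'
#' @param pixels numeric matrix of intensities.
#' @param mask logical matrix, same shape; `TRUE` marks trusted pixels.
#'   Default: all trusted.
#' @param beam_center numeric length-2 `(row, col)` position of the direct
#'   beam, 1-based pixel units; must lie inside the grid. Default: grid
#'   center.
#' @param frame_id opaque identifier string.
#' @return an object of class `detector_frame` with fields `pixels`, `mask`,
#'   `beam_center`, `frame_id`.
#' @export
detector_frame <- function(pixels, mask = NULL, beam_center = NULL,
                           frame_id = "f1") {
  abort_if(!is.matrix(pixels), "pixels must be a matrix")
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  abort_if(!identical(dim(mask), dim(pixels)),
           "pixels and mask must have identical shape")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (is.null(beam_center)) {
    beam_center <- (dim(pixels) + 1) / 2
  }
  abort_if(length(beam_center) != 2 ||
             beam_center[1] < 1 || beam_center[1] > nrow(pixels) ||
             beam_center[2] < 1 || beam_center[2] > ncol(pixels),
           "beam_center must lie inside the pixel grid")
  pixels[!mask] <- 0
  structure(list(pixels = pixels, mask = mask,
                 beam_center = as.numeric(beam_center),
                 frame_id = as.character(frame_id)),
            class = "detector_frame")
}

#' Construct a frame stack
#'
#' An ordered collection of [detector_frame()] objects sharing one shape,
#' mask and beam-center convention.
#'
#' @param frames non-empty list of `detector_frame` objects.
#' @param source_tag experiment label (for synthetic data, the profile name).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, source_tag = "") {
  abort_if(length(frames) == 0, "frame stack must be non-empty")
  abort_if(!all(vapply(frames, inherits, logical(1), "detector_frame")),
           "all elements must be detector_frame objects")
  shp <- dim(frames[[1]]$pixels)
  ok <- vapply(frames, function(f) identical(dim(f$pixels), shp), logical(1))
  abort_if(!all(ok), "all frames must share one shape")
  ids <- vapply(frames, function(f) f$frame_id, character(1))
  abort_if(anyDuplicated(ids) > 0, "frame_ids must be unique within a stack")
  structure(list(frames = frames, source_tag = as.character(source_tag)),
            class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' @export
print.frame_stack <- function(x, ...) {
  shp <- dim(x$frames[[1]]$pixels)
  cat(sprintf("frame_stack: %d frames of %d x %d (source_tag = '%s')\n",
              length(x$frames), shp[1], shp[2], x$source_tag))
  invisible(x)
}

#' @noRd
stack_ids <- function(stack) {
  vapply(stack$frames, function(f) f$frame_id, character(1))
}

#' Write a frame stack to HDF5
#'
#' Raw detector stacks are stored as 4-byte signed integers (values are
#' rounded), so [read_frame_stack()] reproduces an integer-valued stack
#' bit-exactly. Derived real-valued stacks (e.g. contrast-normalized images)
#' can be stored with `storage = "float32"` instead.
#'
#' @param stack a [frame_stack()].
#' @param path destination file path.
#' @param storage `"int32"` (default) or `"float32"`.
#' @return `invisible(path)`.
#' @export
write_frame_stack <- function(stack, path, storage = "int32") {
  abort_if(!inherits(stack, "frame_stack"), "stack must be a frame_stack")
  frames <- lapply(stack$frames, function(f) f$pixels)
  mask <- stack$frames[[1]]$mask
  mask_int <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  bc <- stack$frames[[1]]$beam_center
  .h5_write_stack(path, frames, mask_int, stack_ids(stack), bc[1], bc[2],
                  stack$source_tag, storage)
  invisible(path)
}

#' Read a frame stack from HDF5
#'
#' @param path path to an HDF5 file following the package layout (see
#'   [write_frame_stack()]). A missing `/mask` dataset implies an all-trusted
#'   mask; a mask whose shape differs from the frames is a format error.
#' @return a [frame_stack()] with frames in stored order.
#' @export
read_frame_stack <- function(path) {
  abort_if(!file.exists(path), "file '%s' does not exist", path)
  raw <- .h5_read_stack(path)
  H <- nrow(raw$frames[[1]])
  W <- ncol(raw$frames[[1]])
  mask <- if (is.null(raw$mask)) {
    matrix(TRUE, H, W)
  } else {
    matrix(raw$mask != 0L, H, W)
  }
  bc <- c(raw$beam_center_row, raw$beam_center_col)
  frames <- lapply(seq_along(raw$frames), function(k) {
    detector_frame(raw$frames[[k]], mask = mask, beam_center = bc,
                   frame_id = raw$frame_ids[k])
  })
  frame_stack(frames, source_tag = raw$source_tag)
}

#' Construct an annotation table
#'
#' Per-frame ground truth: a label in `Hit`/`Maybe`/`Miss`, an optional
#' Bragg-spot count, and the annotation provenance. When `source` is
#' `"rule"` the label must be consistent with the spot count under
#' [label_from_spot_count()].
#'
#' @param frame_id character vector of unique frame identifiers.
#' @param label labels, case-insensitive, one of Hit/Maybe/Miss.
#' @param spot_count nonnegative integer counts or `NA`.
#' @param source one of `"expert"`, `"rule"`, `"spotfinder"` per row.
#' @return a `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(frame_id, label, spot_count = NA_integer_,
                             source = "expert") {
  frame_id <- as.character(frame_id)
  abort_if(anyDuplicated(frame_id) > 0, "duplicate frame_id in annotations")
  label <- canonical_labels(label)
  abort_if(anyNA(label), "labels must not be missing")
  n <- length(frame_id)
  spot_count <- suppressWarnings(as.integer(rep_len(spot_count, n)))
  abort_if(any(!is.na(spot_count) & spot_count < 0),
           "spot_count must be nonnegative")
  source <- rep_len(as.character(source), n)
  abort_if(!all(source %in% c("expert", "rule", "spotfinder")),
           "source must be expert, rule or spotfinder")
  rule <- source == "rule"
  if (any(rule)) {
    abort_if(any(is.na(spot_count[rule])),
             "rule-sourced rows must carry a spot_count")
    implied <- label_from_spot_count(spot_count[rule])
    abort_if(!all(implied == label[rule]),
             "rule-sourced labels inconsistent with spot_count")
  }
  structure(data.frame(frame_id = frame_id, label = label,
                       spot_count = spot_count, source = source,
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Read / write annotation tables (CSV)
#'
#' CSV header is `frame_id,label,spot_count,source`; an empty `spot_count`
#' is allowed. Labels are parsed case-insensitively; duplicated frame ids or
#' unknown label strings raise errors.
#'
#' @param path CSV file path.
#' @return [read_annotations()] returns an [annotation_table()];
#'   [write_annotations()] returns `invisible(path)`.
#' @export
read_annotations <- function(path) {
  abort_if(!file.exists(path), "file '%s' does not exist", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "label", "spot_count", "source")
  abort_if(!all(need %in% names(df)),
           "annotation CSV must have columns %s", paste(need, collapse = ","))
  annotation_table(df$frame_id, df$label, df$spot_count, df$source)
}

#' @param table an [annotation_table()].
#' @rdname read_annotations
#' @export
write_annotations <- function(table, path) {
  abort_if(!inherits(table, "annotation_table"),
           "table must be an annotation_table")
  out <- data.frame(frame_id = table$frame_id,
                    label = as.character(table$label),
                    spot_count = table$spot_count,
                    source = table$source)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Train/validation/test split specification
#'
#' @param fractions numeric length-3 `(train, validation, test)` fractions
#'   summing to 1. Default `c(0.5, 0.2, 0.3)`.
#' @param seed integer seed for the split permutation.
#' @param ratio_preserving if `TRUE` (default) each part preserves the whole
#'   table's Hit:Maybe:Miss proportions to within one frame per class.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.5, 0.2, 0.3), seed = 1L,
                       ratio_preserving = TRUE) {
  abort_if(length(fractions) != 3 || any(fractions < 0) || any(fractions > 1),
           "fractions must be three values in [0, 1]")
  abort_if(abs(sum(fractions) - 1) > 1e-8, "fractions must sum to 1")
  structure(list(fractions = as.numeric(fractions), seed = as.integer(seed),
                 ratio_preserving = isTRUE(ratio_preserving)),
            class = "split_spec")
}

# Contiguous slicing of a seeded pseudo-random permutation (Mersenne-Twister);
# boundaries by rounded cumulative fractions so the parts are exhaustive.
#' @noRd
split_indices <- function(n, fractions) {
  bounds <- round(cumsum(fractions) * n)
  bounds[3] <- n
  list(train = seq_len(bounds[1]),
       validation = if (bounds[2] > bounds[1]) (bounds[1] + 1):bounds[2] else integer(0),
       test = if (bounds[3] > bounds[2]) (bounds[2] + 1):bounds[3] else integer(0))
}

#' Deterministically split an annotation table
#'
#' Applies a single seeded pseudo-random permutation (Mersenne-Twister)
#' followed by contiguous slicing. With `ratio_preserving` the permutation
#' and slicing are applied within each class, so every part matches the whole
#' table's class proportions to within one frame per class. The default
#' fractions are 50/20/30 train/validation/test.
#'
#' @param table an [annotation_table()].
#' @param spec a [split_spec()].
#' @return named list of three `annotation_table`s: `train`, `validation`,
#'   `test`; a disjoint, exhaustive partition of `table`.
#' @export
split_dataset <- function(table, spec = split_spec()) {
  abort_if(!inherits(table, "annotation_table"),
           "table must be an annotation_table")
  abort_if(nrow(table) == 0, "table must be non-empty")
  abort_if(!inherits(spec, "split_spec"), "spec must be a split_spec")
  pick <- with_seed(spec$seed, {
    if (spec$ratio_preserving) {
      parts <- list(train = integer(0), validation = integer(0),
                    test = integer(0))
      for (cl in levels(table$label)) {
        rows <- which(table$label == cl)
        if (length(rows) == 0) next
        perm <- rows[sample.int(length(rows))]
        sl <- split_indices(length(rows), spec$fractions)
        for (p in names(parts)) parts[[p]] <- c(parts[[p]], perm[sl[[p]]])
      }
      parts
    } else {
      perm <- sample.int(nrow(table))
      sl <- split_indices(nrow(table), spec$fractions)
      lapply(sl, function(ix) perm[ix])
    }
  })
  lapply(pick, function(ix) {
    ix <- sort(ix)
    structure(table[ix, , drop = FALSE],
              class = c("annotation_table", "data.frame"))
  })
}

#' Randomly subsample a training table, preserving class balance
#'
#' Reduces the table to `n` rows by seeded random sub-selection while keeping
#' each class's share within one frame of its share in the full table
#' (largest-remainder apportionment).
#'
#' @param table an [annotation_table()].
#' @param n target number of rows, `n <= nrow(table)`.
#' @param seed integer seed.
#' @return an `annotation_table` with `n` rows.
#' @export
subsample_training <- function(table, n, seed = 1L) {
  abort_if(!inherits(table, "annotation_table"),
           "table must be an annotation_table")
  abort_if(!is_count(n) || n > nrow(table),
           "n must be a nonnegative integer <= nrow(table)")
  counts <- table(table$label)
  quota <- counts * n / nrow(table)
  take <- floor(quota)
  rem <- n - sum(take)
  if (rem > 0) {
    eligible <- which(take < counts)
    order_rem <- eligible[order((quota - take)[eligible], decreasing = TRUE)]
    take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1
  }
  ix <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(table$label == cl)
      if (take[[cl]] == 0) return(integer(0))
      rows[sample.int(length(rows), take[[cl]])]
    }))
  })
  ix <- sort(ix)
  structure(table[ix, , drop = FALSE],
            class = c("annotation_table", "data.frame"))
}
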