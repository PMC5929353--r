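# Internal helpers shared across modules.

CLASS_LEVELS <- c("Hit", "Maybe", "Miss")

#' @noRd
abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Canonicalize a label vector (case-insensitive) to the Hit/Maybe/Miss
# enumeration; errors on anything else.
#' @noRd
canonical_labels <- function(x) {
  lx <- tolower(as.character(x))
  idx <- match(lx, tolower(CLASS_LEVELS))
  bad <- is.na(idx) & !is.na(lx)
  abort_if(any(bad), "unknown label string(s): %s",
           paste(unique(x[bad]), collapse = ", "))
  factor(CLASS_LEVELS[idx], levels = CLASS_LEVELS)
}

# Stable integer class codes (Hit = 0, Maybe = 1, Miss = 2), the ordering of
# the classification vector.
#' @noRd
label_code <- function(labels) as.integer(canonical_labels(labels)) - 1L

# Derive a child RNG seed from a base seed and a stream offset, kept within
# 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483647)
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}
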