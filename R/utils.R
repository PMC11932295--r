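# Internal helpers shared across modules.

# Structured error: every condition carries a specific class plus
# "cadmilume_error" so callers can catch the whole family.
clStop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cadmilume_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based pixel coordinates: pixel at matrix position [i, j] (1-based) has
# center (x, y) = (j - 1, i - 1); x rightward, y downward, origin top-left.

# Bounding-box pixel selection around a disk center (0-based cx, cy).
# Returns list(rows, cols, d) where d is the |box| x 1 distance matrix
# (rows x cols) from the continuous center.
.diskBox <- function(h, w, cx, cy, r) {
  rows <- max(1L, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
  if (length(rows) == 0L || length(cols) == 0L) {
    return(list(rows = integer(0), cols = integer(0), d = matrix(0, 0, 0)))
  }
  d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`))
  list(rows = rows, cols = cols, d = d)
}
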