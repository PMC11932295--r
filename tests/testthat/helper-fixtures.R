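# Programmatic fixtures shared across the test files.

# Logical disk mask in an h x w frame; center (cx, cy) in 0-based pixel
# coordinates.
diskMask <- function(h, w, cx, cy, r) {
  d <- sqrt(outer((seq_len(h) - 1 - cy)^2, (seq_len(w) - 1 - cx)^2, `+`))
  d <= r
}

# RGB image (counts array) with a uniform background and optional disks.
# disks: list of list(cx, cy, r, rgb).
makeImage <- function(h, w, background = c(0, 0, 0), disks = list(),
                      bit_depth = 8L) {
  px <- array(rep(background, each = h * w), c(h, w, 3))
  for (d in disks) {
    m <- diskMask(h, w, d$cx, d$cy, d$r)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- d$rgb[ch]
      px[, , ch] <- plane
    }
  }
  PlateImage(px, bit_depth)
}

# Fake detection table from known well geometry (for assignGrid tests).
fakeDetections <- function(cx, cy, r) {
  det <- data.frame(center_x = cx, center_y = cy, radius = r,
                    area = pi * r^2, circularity = 1,
                    grid_row = NA_integer_, grid_col = NA_integer_)
  det[order(det$center_y, det$center_x), ]
}

# Sample-well truth lookup: per-well absolute relative deviation (%) of the
# pipeline estimates against the generator's ground truth.
sampleRecoveryErrors <- function(report) {
  w <- wellMeasurements(report)
  tr <- provenance(report)$truth
  samp <- w$role == "sample"
  truth <- tr$conc_mM[match(paste(w$row[samp], w$col[samp]),
                            paste(tr$grid_row, tr$grid_col))]
  abs(w$conc_mM[samp] - truth) / truth * 100
}
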