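#' Collapse an RGB image to the detection channel
#'
#' Wells are detected on the per-pixel maximum over the three channels. Unlike
#' a luminance weighting, the channel maximum treats green wells (low cadmium)
#' and orange wells (high cadmium) symmetrically, so the segmentation is not
#' biased toward either end of the calibration range.
#'
#' @param image a [PlateImage-class].
#' @return A `height x width` numeric matrix of counts with attribute
#'   `bit_depth`.
#' @export
detectionChannel <- function(image) {
  if (!is(image, "PlateImage"))
    clStop("cadmilume_input_error", "detectionChannel expects a PlateImage")
  p <- image@pixels
  ch <- pmax(p[, , 1], p[, , 2], p[, , 3])
  attr(ch, "bit_depth") <- image@bitDepth
  ch
}

#' Otsu threshold of an integer-valued intensity grid
#'
#' Exhaustive scan of the intensity histogram for the threshold maximizing the
#' between-class variance; on a plateau of equally optimal thresholds the
#' plateau midpoint is returned. Foreground is everything strictly above the
#' threshold.
#'
#' @param channel numeric matrix of integer-valued intensities.
#' @param levels number of grey levels (256 for 8-bit, 65536 for 16-bit).
#' @return The threshold (numeric scalar).
#' @export
otsuThreshold <- function(channel, levels = 256L) {
  v <- floor(as.numeric(channel))
  if (min(v) == max(v))
    clStop("cadmilume_degenerate_histogram_error",
           "constant-intensity image: no two classes to separate")
  h <- tabulate(v + 1L, nbins = levels)
  p <- h / sum(h)
  g <- 0:(levels - 1)
  omega <- cumsum(p)          # mass of the class <= t
  mu <- cumsum(p * g)         # first moment of the class <= t
  mu_t <- mu[levels]
  # between-class variance for threshold t = g[i]; foreground is > t
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sigma_b <- sigma_b[-levels]  # t = max level leaves no foreground
  best <- which(sigma_b == max(sigma_b)) - 1
  mean(best)
}

#' Segment luminescent wells from the background
#'
#' Thresholds the detection channel (Otsu by default, or a fixed threshold)
#' and cleans the mask by morphological opening with a disk, which removes
#' specks smaller than the structuring element.
#'
#' @param channel numeric matrix from [detectionChannel()] (or any
#'   integer-valued intensity grid).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold used when `method = "fixed"`.
#' @param opening_radius radius (pixels) of the opening disk; 0 disables.
#' @param levels grey levels; defaults to the grid's `bit_depth` attribute
#'   (256 when absent).
#' @return A list: `mask` (logical matrix, foreground `TRUE`) and `threshold`.
#' @export
binarizeImage <- function(channel, method = c("otsu", "fixed"),
                          fixed_threshold = NULL, opening_radius = 1,
                          levels = NULL) {
  method <- match.arg(method)
  if (length(channel) == 0L)
    clStop("cadmilume_input_error", "empty intensity grid")
  if (is.null(levels))
    levels <- 2L^(attr(channel, "bit_depth") %||% 8L)
  th <- if (method == "otsu") {
    otsuThreshold(channel, levels)
  } else {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold))
      clStop("cadmilume_input_error",
             "method = 'fixed' requires a finite fixed_threshold")
    fixed_threshold
  }
  mask <- channel > th
  if (opening_radius >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    mask <- EBImage::opening(mask * 1L, brush) > 0
  }
  list(mask = matrix(as.logical(mask), nrow(channel), ncol(channel)),
       threshold = th)
}

# Perimeter per labelled component: count of 4-neighbour foreground/background
# unit edges, corrected by pi/4 (Crofton) so a digital disk of radius r has
# perimeter ~ 2*pi*r rather than the Manhattan 8r.
.componentPerimeter <- function(lab, n_lab) {
  h <- nrow(lab); w <- ncol(lab)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1), 2:(w + 1)] <- lab
  core <- padded[2:(h + 1), 2:(w + 1)]
  fg <- core > 0L
  edges <- numeric(n_lab)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in shifts) {
    nb <- padded[2:(h + 1) + s[1], 2:(w + 1) + s[2]]
    hit <- fg & nb != core
    if (any(hit)) {
      t <- tabulate(core[hit], nbins = n_lab)
      edges <- edges + t
    }
  }
  edges * pi / 4
}

#' Detect well candidates in a binary mask
#'
#' Connected foreground components are measured and filtered by area and
#' circularity. Components are treated as their outer contours: interior
#' holes (pixels that dip below threshold inside a well, e.g. from shot noise)
#' are filled before measurement, so area, centroid and perimeter describe
#' the traced outline. Circularity is `4*pi*area / perimeter^2` with an
#' edge-count perimeter (Crofton-corrected); values slightly above 1 caused
#' by discretization are clamped to 1. The defaults reject dust specks and
#' elongated glare streaks while keeping any plausibly disk-shaped well.
#'
#' @param mask logical matrix from [binarizeImage()].
#' @param min_area minimum component area in pixels^2 (default 100).
#' @param min_circularity minimum circularity (default 0.6).
#' @return A data.frame sorted by (`center_y`, `center_x`) with columns
#'   `center_x`, `center_y` (0-based sub-pixel centroids), `radius`
#'   (equivalent-circle radius `sqrt(area/pi)`), `area`, `circularity`,
#'   `grid_row`, `grid_col` (`NA` until [assignGrid()]). An empty mask gives
#'   an empty data.frame.
#' @export
detectWells <- function(mask, min_area = 100, min_circularity = 0.6) {
  empty <- data.frame(center_x = numeric(0), center_y = numeric(0),
                      radius = numeric(0), area = numeric(0),
                      circularity = numeric(0),
                      grid_row = integer(0), grid_col = integer(0))
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask * 1L) > 0
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n_lab <- max(lab)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  h <- nrow(mask)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  area <- tabulate(labs, nbins = n_lab)
  cy <- rowsum(as.numeric(rows), labs)[, 1] / area - 1
  cx <- rowsum(as.numeric(cols), labs)[, 1] / area - 1
  per <- .componentPerimeter(lab, n_lab)
  circ <- pmin(4 * pi * area / per^2, 1)
  keep <- which(area >= min_area & circ >= min_circularity)
  det <- data.frame(center_x = cx[keep], center_y = cy[keep],
                    radius = sqrt(area[keep] / pi), area = as.numeric(area[keep]),
                    circularity = circ[keep],
                    grid_row = rep(NA_integer_, length(keep)),
                    grid_col = rep(NA_integer_, length(keep)))
  det <- det[order(det$center_y, det$center_x), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Assign detected wells to plate grid positions
#'
#' Rows are recovered by sorting detections by y and splitting wherever the
#' y-gap between consecutive detections exceeds half the median detection
#' diameter; this tolerates the few degrees of rotation a plate can have in a
#' fixed dark box. Within each physical row, detections are ordered by x and
#' mapped left-to-right onto the layout row's non-empty cells; physical rows
#' map top-to-bottom onto layout rows that contain wells.
#'
#' @param detections data.frame from [detectWells()].
#' @param layout a [PlateLayout-class].
#' @return The detections with `grid_row`, `grid_col` filled in (0-based),
#'   plus `role`, `conc_mM` and `label` from the layout; the assignment is a
#'   bijection onto the non-empty layout cells.
#' @export
assignGrid <- function(detections, layout) {
  cells <- nonEmptyCells(layout)
  if (nrow(detections) != nrow(cells))
    clStop("cadmilume_layout_mismatch_error",
           sprintf("detected %d wells but the layout declares %d non-empty cells",
                   nrow(detections), nrow(cells)),
           n_detected = nrow(detections), n_expected = nrow(cells))
  ord <- order(detections$center_y, detections$center_x)
  det <- detections[ord, , drop = FALSE]
  gap <- diff(det$center_y)
  half_diam <- stats::median(2 * det$radius) / 2
  breaks <- which(gap > half_diam)
  group <- cumsum(c(1L, as.integer(seq_along(gap) %in% breaks)))
  layout_rows <- sort(unique(cells$grid_row))
  sizes <- as.integer(table(factor(cells$grid_row, levels = layout_rows)))
  got <- as.integer(table(group))
  if (length(got) != length(sizes) || any(got != sizes))
    clStop("cadmilume_grid_inference_error",
           sprintf("row split found sizes [%s] but the layout expects [%s]",
                   paste(got, collapse = ", "), paste(sizes, collapse = ", ")),
           found = got, expected = sizes)
  det$grid_row <- NA_integer_
  det$grid_col <- NA_integer_
  for (k in seq_along(layout_rows)) {
    in_row <- which(group == k)
    in_row <- in_row[order(det$center_x[in_row])]
    row_cells <- cells[cells$grid_row == layout_rows[k], , drop = FALSE]
    row_cells <- row_cells[order(row_cells$grid_col), , drop = FALSE]
    det$grid_row[in_row] <- row_cells$grid_row
    det$grid_col[in_row] <- row_cells$grid_col
  }
  m <- match(paste(det$grid_row, det$grid_col),
             paste(cells$grid_row, cells$grid_col))
  det$role <- cells$role[m]
  det$conc_mM <- cells$conc_mM[m]
  det$label <- cells$label[m]
  det <- det[order(det$grid_row, det$grid_col), , drop = FALSE]
  rownames(det) <- NULL
  det
}
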