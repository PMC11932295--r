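#' Estimate the local background around a well
#'
#' Per-channel median over an annulus around the well (default 1.2-1.5 well
#' radii), excluding any pixel that falls inside another detected well. Even
#' in a dark box the sensor floor is nonzero (dark current and stray light),
#' so subtracting a local background keeps the green/red ratio unbiased for
#' dim wells.
#'
#' @param image a [PlateImage-class].
#' @param well one-row data.frame (a row of [detectWells()] output).
#' @param detections all detections on the plate (used to exclude well pixels
#'   from the annulus); defaults to `well` alone.
#' @param annulus numeric length-2, inner and outer annulus radii as multiples
#'   of the well radius.
#' @return Numeric length-3 background (counts) in red, green, blue order.
#' @export
estimateBackground <- function(image, well, detections = well,
                               annulus = c(1.2, 1.5)) {
  h <- imageHeight(image); w <- imageWidth(image)
  r <- well$radius
  box <- .diskBox(h, w, well$center_x, well$center_y, annulus[2] * r + 1)
  if (length(box$rows) == 0L)
    clStop("cadmilume_background_unavailable_error",
           "annulus lies entirely outside the image")
  keep <- box$d >= annulus[1] * r & box$d <= annulus[2] * r
  # exclude pixels inside any detected well
  for (i in seq_len(nrow(detections))) {
    di <- sqrt(outer((box$rows - 1 - detections$center_y[i])^2,
                     (box$cols - 1 - detections$center_x[i])^2, `+`))
    keep <- keep & di > detections$radius[i]
  }
  if (!any(keep))
    clStop("cadmilume_background_unavailable_error",
           "no usable background pixels in the annulus")
  vapply(1:3, function(ch) {
    stats::median(image@pixels[box$rows, box$cols, ch][keep])
  }, numeric(1))
}

#' Extract a robust color measurement from a well
#'
#' Per-channel median over the well's core disk (default 0.7 of the detected
#' radius, avoiding the blurred rim), excluding pixels saturated in any
#' channel, then background-subtracted and clamped at zero. The median is
#' preferred to the mean for robustness against residual glare and dust.
#'
#' @param image a [PlateImage-class].
#' @param well one-row data.frame (a row of [detectWells()] output).
#' @param background numeric length-3 from [estimateBackground()] (or zeros).
#' @param core_scale fraction of the detected radius used as the core disk.
#' @param saturation_limit maximum tolerated fraction of saturated core
#'   pixels; above it the measurement is refused because a censored median
#'   would be biased low.
#' @return A [ColorMeasurement-class].
#' @export
extractColor <- function(image, well, background = c(0, 0, 0),
                         core_scale = 0.7, saturation_limit = 0.5) {
  h <- imageHeight(image); w <- imageWidth(image)
  box <- .diskBox(h, w, well$center_x, well$center_y, core_scale * well$radius)
  core <- box$d <= core_scale * well$radius
  if (!any(core))
    clStop("cadmilume_empty_roi_error", "no pixels in the well core")
  full <- fullScale(image)
  px <- lapply(1:3, function(ch) image@pixels[box$rows, box$cols, ch][core])
  sat <- px[[1]] >= full | px[[2]] >= full | px[[3]] >= full
  sat_frac <- mean(sat)
  if (sat_frac > saturation_limit)
    clStop("cadmilume_saturation_error",
           sprintf(paste0("%.0f%% of core pixels are saturated ",
                          "(limit %.0f%%): retake the photo at lower exposure"),
                   100 * sat_frac, 100 * saturation_limit),
           saturated_fraction = sat_frac)
  usable <- !sat
  if (!any(usable))
    clStop("cadmilume_empty_roi_error", "no usable (unsaturated) core pixels")
  med <- vapply(px, function(v) stats::median(v[usable]), numeric(1))
  val <- pmax(med - background, 0)
  new("ColorMeasurement", red = val[1], green = val[2], blue = val[3],
      nPixels = sum(usable), saturatedFraction = sat_frac,
      background = as.numeric(background))
}

#' @rdname ColorMeasurement-class
#' @param object a `ColorMeasurement`.
#' @export
setMethod("show", "ColorMeasurement", function(object) {
  cat(sprintf(
    "ColorMeasurement: RGB (%.1f, %.1f, %.1f), %d px, %.1f%% saturated\n",
    object@red, object@green, object@blue, object@nPixels,
    100 * object@saturatedFraction))
})

#' Normalized chromatic coordinates and green/red ratio
#'
#' Divides each channel by the channel sum, removing overall brightness
#' (exposure, enzyme amount, integration time) from the color, and forms the
#' green/red ratio that the calibration line consumes. The ratio decreases as
#' cadmium shifts the emission from green toward orange.
#'
#' @param measurement a [ColorMeasurement-class] or a numeric length-3 RGB
#'   vector.
#' @return A [ChromaticCoords-class]. A zero-sum input is an error; a zero red
#'   channel raises a ratio-undefined error whose condition carries the
#'   coordinates in its `coords` field.
#' @examples
#' chromaticCoords(c(50, 100, 10))   # ratio 2
#' @export
chromaticCoords <- function(measurement) {
  rgb <- if (is(measurement, "ColorMeasurement")) {
    c(measurement@red, measurement@green, measurement@blue)
  } else as.numeric(measurement)
  if (length(rgb) != 3L || any(!is.finite(rgb)) || any(rgb < 0))
    clStop("cadmilume_input_error", "need three finite non-negative channels")
  s <- sum(rgb)
  if (s <= 0)
    clStop("cadmilume_invalid_color_error",
           "zero-sum measurement: no light to normalize")
  cc <- rgb / s
  ratio <- if (rgb[1] > 0) rgb[2] / rgb[1] else NA_real_
  coords <- new("ChromaticCoords", r = cc[1], g = cc[2], b = cc[3],
                greenRedRatio = ratio)
  if (rgb[1] == 0)
    clStop("cadmilume_ratio_undefined_error",
           "red channel is zero: green/red ratio undefined", coords = coords)
  coords
}

#' @rdname ChromaticCoords-class
#' @param object a `ChromaticCoords`.
#' @export
setMethod("show", "ChromaticCoords", function(object) {
  cat(sprintf("ChromaticCoords: (r, g, b) = (%.4f, %.4f, %.4f), G/R = %s\n",
              object@r, object@g, object@b,
              ifelse(is.na(object@greenRedRatio), "undefined",
                     sprintf("%.4f", object@greenRedRatio))))
})

#' @rdname ChromaticCoords-class
#' @param x a `ChromaticCoords`.
#' @export
setGeneric("greenRedRatio", function(x) standardGeneric("greenRedRatio"))
#' @rdname ChromaticCoords-class
#' @export
setMethod("greenRedRatio", "ChromaticCoords", function(x) x@greenRedRatio)
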