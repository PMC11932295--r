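#' @import methods
NULL

#' RGB plate photograph
#'
#' An in-memory RGB raster of a dark-box plate photograph. Pixels are stored
#' as a numeric `height x width x 3` array of integer-valued counts in
#' red, green, blue channel order, on the native scale of the sensor
#' (`[0, 2^bitDepth - 1]`). Pixel coordinates used throughout the package are
#' 0-based with the origin at the top-left corner, x increasing rightward and
#' y increasing downward.
#'
#' @slot pixels numeric array `[height, width, 3]` of per-channel counts.
#' @slot bitDepth integer, 8 or 16.
#' @export
setClass("PlateImage",
  representation(pixels = "array", bitDepth = "integer"))

setValidity("PlateImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L) return("pixels must be a 3-dimensional array")
  if (dim(p)[3] != 3L) return("pixels must have 3 channels (red, green, blue)")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  full <- 2^object@bitDepth - 1
  rng <- range(p)
  if (rng[1] < 0 || rng[2] > full)
    return(sprintf("pixel intensities must lie in [0, %d]", full))
  TRUE
})

#' Plate layout: grid geometry and per-well roles
#'
#' Describes an assay plate as an `nRows x nCols` grid in which each cell is a
#' water control, a cadmium standard of known concentration (mM), an unknown
#' sample, or empty. Controls are calibration points at 0 mM. Grid indices in
#' all user-facing tables are 0-based (row 0 is the top row).
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot roles character matrix, each cell one of `"control"`, `"standard"`,
#'   `"sample"`, `"empty"`.
#' @slot conc numeric matrix of standard concentrations in mM (0 for controls,
#'   `NA` elsewhere).
#' @slot labels character matrix of well labels (e.g. `"S1"`).
#' @export
setClass("PlateLayout",
  representation(nRows = "integer", nCols = "integer",
                 roles = "matrix", conc = "matrix", labels = "matrix"))

setValidity("PlateLayout", function(object) {
  ok_roles <- c("control", "standard", "sample", "empty")
  if (!all(dim(object@roles) == c(object@nRows, object@nCols)))
    return("roles matrix dimensions must match nRows x nCols")
  bad <- !object@roles %in% ok_roles
  if (any(bad))
    return(sprintf("unknown role '%s'", object@roles[which(bad)[1]]))
  is_std <- object@roles == "standard"
  if (any(is_std & (!is.finite(object@conc) | object@conc < 0)))
    return("every standard well must carry a finite concentration >= 0 mM")
  n_cal <- sum(object@roles %in% c("control", "standard"))
  if (n_cal < 3L)
    return("at least 3 control/standard wells are required for calibration")
  TRUE
})

#' Robust per-well color measurement
#'
#' Background-subtracted channel medians over the core of a detected well,
#' with bookkeeping for saturation screening.
#'
#' @slot red,green,blue numeric, background-subtracted median counts (>= 0).
#' @slot nPixels integer, number of core pixels used.
#' @slot saturatedFraction numeric in `[0, 1]`, fraction of core pixels
#'   excluded because they were saturated in at least one channel.
#' @slot background numeric length-3, the per-channel background subtracted.
#' @export
setClass("ColorMeasurement",
  representation(red = "numeric", green = "numeric", blue = "numeric",
                 nPixels = "integer", saturatedFraction = "numeric",
                 background = "numeric"))

setValidity("ColorMeasurement", function(object) {
  if (object@nPixels < 1L) return("nPixels must be >= 1")
  if (min(object@red, object@green, object@blue) < 0)
    return("channel values must be >= 0")
  if (object@saturatedFraction < 0 || object@saturatedFraction > 1)
    return("saturatedFraction must lie in [0, 1]")
  TRUE
})

#' Normalized chromatic coordinates and the green/red ratio
#'
#' Channel intensities normalized by their sum: `r = R/(R+G+B)` etc., so that
#' `r + g + b = 1` and the coordinates are invariant to overall exposure. The
#' green/red ratio `G/R` (equivalently `g/r`) is the assay's readout.
#'
#' @slot r,g,b numeric normalized coordinates in `[0, 1]`, summing to 1.
#' @slot greenRedRatio numeric, `G/R`; `NA` when red is 0.
#' @export
setClass("ChromaticCoords",
  representation(r = "numeric", g = "numeric", b = "numeric",
                 greenRedRatio = "numeric"))

setValidity("ChromaticCoords", function(object) {
  s <- object@r + object@g + object@b
  if (abs(s - 1) > 1e-9) return("chromatic coordinates must sum to 1")
  if (min(object@r, object@g, object@b) < 0 ||
      max(object@r, object@g, object@b) > 1)
    return("chromatic coordinates must lie in [0, 1]")
  TRUE
})

#' Linear ratio-versus-concentration calibration
#'
#' Ordinary least squares fit of the green/red ratio on cadmium concentration,
#' `ratio = beta0 + beta1 * C`, over the plate's control and standard wells.
#' The slope must be negative: green emission decreases as cadmium binds, so a
#' non-negative slope signals assay failure or mislabelled wells.
#'
#' @slot beta0 numeric intercept (ratio at 0 mM).
#' @slot beta1 numeric slope per mM (< 0).
#' @slot rSquared numeric coefficient of determination.
#' @slot residualSD numeric residual standard deviation `sqrt(SSE/(n-2))`.
#' @slot nPoints integer number of calibration points.
#' @slot concRange numeric length-2, `[min C, max C]` of the standards (mM).
#' @slot meanRatio numeric mean of the calibration ratios.
#' @slot sxx numeric `sum((C - mean(C))^2)` in mM^2.
#' @export
setClass("CalibrationModel",
  representation(beta0 = "numeric", beta1 = "numeric", rSquared = "numeric",
                 residualSD = "numeric", nPoints = "integer",
                 concRange = "numeric", meanRatio = "numeric", sxx = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@nPoints < 3L) return("calibration needs at least 3 points")
  if (!is.finite(object@beta1) || object@beta1 >= 0)
    return("calibration slope must be negative (ratio decreases with cadmium)")
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    return("rSquared must lie in [0, 1]")
  if (object@residualSD < 0) return("residualSD must be >= 0")
  if (length(object@concRange) != 2L || object@concRange[1] >= object@concRange[2])
    return("concRange must be [c_min, c_max] with c_min < c_max")
  TRUE
})

#' Two-peak bioluminescence emission model
#'
#' Ground-truth color model for the synthetic renderer. The enzyme's emission
#' is represented as green and red-shifted Gaussian peaks; the camera-level
#' green/red ratio follows the assay's linear law
#' `ratio(C) = ratio0 + ratioSlope * C`. In `"ratio_linear"` mode the channel
#' values are set directly from the ratio; in `"spectral"` mode a two-peak
#' mixture spectrum is solved so that the camera-integrated ratio matches the
#' same line.
#'
#' @slot lambdaGreen,lambdaRed numeric peak wavelengths in nm (green < red).
#' @slot sigmaPeak numeric Gaussian peak width (sd) in nm.
#' @slot ratio0 numeric green/red ratio at 0 mM.
#' @slot ratioSlope numeric ratio change per mM (< 0).
#' @slot mode character, `"ratio_linear"` or `"spectral"`.
#' @export
setClass("EmissionModel",
  representation(lambdaGreen = "numeric", lambdaRed = "numeric",
                 sigmaPeak = "numeric", ratio0 = "numeric",
                 ratioSlope = "numeric", mode = "character"))

setValidity("EmissionModel", function(object) {
  if (object@lambdaGreen >= object@lambdaRed)
    return("lambdaGreen must be smaller than lambdaRed")
  if (object@sigmaPeak <= 0) return("sigmaPeak must be positive")
  if (!object@mode %in% c("ratio_linear", "spectral"))
    return("mode must be 'ratio_linear' or 'spectral'")
  TRUE
})

#' Full generative description of a synthetic plate photograph
#'
#' Everything needed to render a seeded, physically motivated plate image with
#' known per-well cadmium concentrations: layout and truth concentrations,
#' emission model, camera exposure, grid geometry, and a CCD-style noise model
#' (Poisson photon noise plus Gaussian read noise over a dark floor).
#' Identical spec and seed give a bit-identical image.
#'
#' @slot layout a [PlateLayout-class].
#' @slot concentrations numeric matrix of true per-well concentrations (mM).
#' @slot emission an [EmissionModel-class].
#' @slot exposure numeric camera gain: red-channel counts per unit emission.
#' @slot wellRadius,pitch numeric well radius and grid pitch in pixels
#'   (pitch >= 3 * radius so wells never overlap).
#' @slot origin numeric length-2, (x, y) of the grid's top-left well center.
#' @slot rotation numeric plate rotation in degrees about the image center.
#' @slot jitterSD numeric per-well center jitter (sd, pixels).
#' @slot photonGain numeric counts per photon-equivalent.
#' @slot readSD numeric Gaussian read noise sd in counts.
#' @slot backgroundLevel numeric dark floor in counts.
#' @slot imageWidth,imageHeight,bitDepth,seed integers.
#' @export
setClass("SyntheticPlateSpec",
  representation(layout = "PlateLayout", concentrations = "matrix",
                 emission = "EmissionModel", exposure = "numeric",
                 wellRadius = "numeric", pitch = "numeric", origin = "numeric",
                 rotation = "numeric", jitterSD = "numeric",
                 photonGain = "numeric", readSD = "numeric",
                 backgroundLevel = "numeric", imageWidth = "integer",
                 imageHeight = "integer", bitDepth = "integer",
                 seed = "integer"))

setValidity("SyntheticPlateSpec", function(object) {
  if (object@pitch < 3 * object@wellRadius)
    return("pitch must be >= 3 * wellRadius (wells must not overlap)")
  if (object@exposure <= 0) return("exposure must be positive")
  if (object@photonGain < 0 || object@readSD < 0 || object@backgroundLevel < 0)
    return("noise parameters must be >= 0")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  cells <- nonEmptyCells(object@layout)
  conc <- object@concentrations[cbind(cells$grid_row + 1L, cells$grid_col + 1L)]
  if (any(!is.finite(conc) | conc < 0))
    return("every non-empty well needs a finite true concentration >= 0 mM")
  # ratio must stay positive over the configured concentration range
  rho_min <- object@emission@ratio0 + object@emission@ratioSlope * max(conc)
  if (rho_min <= 0)
    return("green/red ratio becomes non-positive at the maximum concentration")
  ctr <- .wellCenters(object)
  margin <- object@wellRadius + 4 * max(object@jitterSD, 1)
  if (any(ctr$x < margin - 0.5) || any(ctr$x > object@imageWidth - 1 - margin + 0.5) ||
      any(ctr$y < margin - 0.5) || any(ctr$y > object@imageHeight - 1 - margin + 0.5))
    return("wells (including jitter margin) must lie inside the image frame")
  TRUE
})

#' End-to-end analysis report
#'
#' One record per non-empty layout cell (ordered by grid position) with the
#' extracted color, green/red ratio, and, for sample wells, the estimated
#' cadmium concentration with its inverse-prediction standard error and range
#' flag; plus the fitted calibration and run provenance.
#'
#' @slot wells data.frame of per-well records.
#' @slot calibration the fitted [CalibrationModel-class].
#' @slot provenance list: input description, parameter values, package
#'   version, detection threshold.
#' @export
setClass("AnalysisReport",
  representation(wells = "data.frame", calibration = "CalibrationModel",
                 provenance = "list"))
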