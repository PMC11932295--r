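#' Default analysis parameters
#'
#' @return Named list of the tunable detection/extraction parameters with
#'   their defaults.
#' @export
defaultParams <- function() {
  list(threshold_method = "otsu", fixed_threshold = NULL, opening_radius = 1,
       min_area = 100, min_circularity = 0.6, core_scale = 0.7,
       annulus = c(1.2, 1.5), saturation_limit = 0.5,
       concentration_factor = NULL, ppm_basis = "cdso4")
}

#' Run the full plate-analysis pipeline
#'
#' Detection -> grid assignment -> background and color extraction ->
#' calibration fit on the control/standard wells -> inverse prediction for
#' the sample wells -> report. A per-well failure (saturation, undefined
#' ratio, empty ROI) flags that well `invalid` without aborting the run; a
#' calibration failure aborts with the calibration diagnostics, since no
#' concentration can be reported without a valid line.
#'
#' @param input a [PlateImage-class] (with `layout`), or a
#'   [SyntheticPlateSpec-class], which is rendered first (its layout and
#'   ground truth are carried along; the truth table is attached to the
#'   provenance for self-tests).
#' @param layout a [PlateLayout-class]; ignored for synthetic input, which
#'   carries its own layout.
#' @param params named list overriding [defaultParams()].
#' @return An [AnalysisReport-class].
#' @examples
#' report <- runPipeline(plateSpec(seed = 7))
#' wellMeasurements(report)[, c("row", "col", "role", "ratio", "conc_mM")]
#' @export
runPipeline <- function(input, layout = NULL, params = list()) {
  p <- utils::modifyList(defaultParams(), params)
  truth <- NULL
  input_desc <- NULL
  if (is(input, "SyntheticPlateSpec")) {
    rendered <- renderPlate(input)
    image <- rendered$image
    truth <- rendered$truth
    layout <- input@layout
    input_desc <- list(type = "synthetic", spec = .specProvenance(input))
  } else if (is(input, "PlateImage")) {
    image <- input
    if (is.null(layout))
      clStop("cadmilume_input_error", "a plate image needs a layout")
    input_desc <- list(type = "image",
                       size = c(imageWidth(image), imageHeight(image)),
                       bit_depth = bitDepth(image))
  } else {
    clStop("cadmilume_input_error",
           "input must be a PlateImage or a SyntheticPlateSpec")
  }

  channel <- detectionChannel(image)
  bin <- binarizeImage(channel, method = p$threshold_method,
                       fixed_threshold = p$fixed_threshold,
                       opening_radius = p$opening_radius)
  det <- detectWells(bin$mask, min_area = p$min_area,
                     min_circularity = p$min_circularity)
  det <- assignGrid(det, layout)

  n <- nrow(det)
  meas <- data.frame(R = rep(NA_real_, n), G = NA_real_, B = NA_real_,
                     chrom_r = NA_real_, chrom_g = NA_real_, chrom_b = NA_real_,
                     ratio = NA_real_, n_pixels = NA_integer_,
                     saturated_fraction = NA_real_)
  well_ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      bg <- estimateBackground(image, det[i, ], det, annulus = p$annulus)
      cm <- extractColor(image, det[i, ], bg, core_scale = p$core_scale,
                         saturation_limit = p$saturation_limit)
      cc <- chromaticCoords(cm)
      list(cm = cm, cc = cc)
    }, cadmilume_error = function(e) e)
    if (inherits(res, "error")) {
      well_ok[i] <- FALSE
      next
    }
    meas$R[i] <- res$cm@red; meas$G[i] <- res$cm@green; meas$B[i] <- res$cm@blue
    meas$chrom_r[i] <- res$cc@r; meas$chrom_g[i] <- res$cc@g
    meas$chrom_b[i] <- res$cc@b
    meas$ratio[i] <- res$cc@greenRedRatio
    meas$n_pixels[i] <- res$cm@nPixels
    meas$saturated_fraction[i] <- res$cm@saturatedFraction
  }

  is_cal <- det$role %in% c("control", "standard")
  cal_ok <- is_cal & well_ok & is.finite(meas$ratio)
  model <- tryCatch(
    fitCalibration(det$conc_mM[cal_ok], meas$ratio[cal_ok]),
    cadmilume_error = function(e) {
      clStop("cadmilume_run_error",
             sprintf("calibration failed: %s", conditionMessage(e)),
             calibration_error = e)
    })

  wells <- data.frame(row = det$grid_row, col = det$grid_col,
                      role = det$role, label = det$label, meas,
                      conc_mM = NA_real_, se_mM = NA_real_,
                      flag = "calibration", stringsAsFactors = FALSE)
  is_samp <- det$role == "sample"
  if (any(is_samp)) {
    pred <- predictConcentration(model, meas$ratio[is_samp],
                                 det$label[is_samp])
    wells$conc_mM[is_samp] <- pred$concentration
    wells$se_mM[is_samp] <- pred$std_error
    wells$flag[is_samp] <- pred$flag
  }
  wells$flag[!well_ok] <- "invalid"

  cf <- p$concentration_factor
  wells$orig_conc_uM <- if (!is.null(cf)) wells$conc_mM / cf * 1000 else NA_real_
  wells$ppm <- ifelse(is.na(wells$conc_mM), NA_real_,
                      mmToPpm(pmax(wells$conc_mM, 0), basis = p$ppm_basis))

  prov <- list(package_version = as.character(utils::packageVersion("cadmilume")),
               input = input_desc,
               params = p[!vapply(p, is.null, logical(1))],
               detection_threshold = bin$threshold,
               n_detections = n,
               detections = det[, c("center_x", "center_y", "radius", "area",
                                    "circularity", "grid_row", "grid_col")])
  if (!is.null(truth)) prov$truth <- truth
  new("AnalysisReport", wells = wells, calibration = model, provenance = prov)
}

# Serializable description of a synthetic spec (provenance; no pixel data).
.specProvenance <- function(spec) {
  list(seed = spec@seed, mode = spec@emission@mode,
       exposure = spec@exposure, well_radius = spec@wellRadius,
       pitch = spec@pitch, origin = spec@origin, rotation = spec@rotation,
       jitter_sd = spec@jitterSD, photon_gain = spec@photonGain,
       read_sd = spec@readSD, background_level = spec@backgroundLevel,
       size = c(spec@imageWidth, spec@imageHeight),
       bit_depth = spec@bitDepth,
       ratio0 = spec@emission@ratio0, ratio_slope = spec@emission@ratioSlope)
}

#' @rdname AnalysisReport-class
#' @param x,object an `AnalysisReport`.
#' @export
setGeneric("wellMeasurements", function(x) standardGeneric("wellMeasurements"))
#' @rdname AnalysisReport-class
#' @export
setMethod("wellMeasurements", "AnalysisReport", function(x) x@wells)
#' @rdname AnalysisReport-class
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname AnalysisReport-class
#' @export
setMethod("calibration", "AnalysisReport", function(x) x@calibration)
#' @rdname AnalysisReport-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname AnalysisReport-class
#' @export
setMethod("provenance", "AnalysisReport", function(x) x@provenance)

#' @rdname AnalysisReport-class
#' @export
setMethod("show", "AnalysisReport", function(object) {
  w <- object@wells
  cat(sprintf("AnalysisReport: %d wells (%d sample)\n", nrow(w),
              sum(w$role == "sample")))
  show(object@calibration)
  samp <- w[w$role == "sample", , drop = FALSE]
  if (nrow(samp)) {
    cat("Sample estimates (mM):\n")
    print(data.frame(label = samp$label, ratio = round(samp$ratio, 4),
                     conc_mM = round(samp$conc_mM, 4),
                     se_mM = round(samp$se_mM, 4), flag = samp$flag,
                     row.names = NULL))
  }
})

#' Write the per-well report table as CSV
#'
#' Columns: `row`, `col`, `role`, `label`, `ratio`, `conc_mM`, `se_mM`,
#' `flag`, `orig_conc_uM`, `ppm`; one row per non-empty layout cell, ordered
#' by grid position. Identical inputs and parameters give a byte-identical
#' file.
#'
#' @param report an [AnalysisReport-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeReportCSV <- function(report, path) {
  cols <- c("row", "col", "role", "label", "ratio", "conc_mM", "se_mM",
            "flag", "orig_conc_uM", "ppm")
  utils::write.csv(report@wells[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write the full report (wells, calibration, provenance) as JSON
#'
#' @param report an [AnalysisReport-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  m <- report@calibration
  prov <- report@provenance
  prov$truth <- NULL  # self-test payload, not part of the public report
  jsonlite::write_json(
    list(wells = report@wells,
         calibration = list(beta0 = m@beta0, beta1 = m@beta1,
                            r_squared = m@rSquared, residual_sd = m@residualSD,
                            n_points = m@nPoints, conc_range = m@concRange,
                            mean_ratio = m@meanRatio, sxx = m@sxx),
         provenance = prov),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write an annotated overlay image
#'
#' Draws the analyzed photograph with each detected well outlined (green for
#' calibration wells, white for in-range samples, orange for out-of-range,
#' red for invalid) and labelled with its estimated concentration in mM.
#'
#' @param report an [AnalysisReport-class].
#' @param image the analyzed [PlateImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
annotateReport <- function(report, image, path) {
  w <- imageWidth(image); h <- imageHeight(image)
  wells <- report@wells
  det <- report@provenance$detections
  m <- match(paste(wells$row, wells$col), paste(det$grid_row, det$grid_col))
  cx <- det$center_x[m]; cy <- det$center_y[m]; rad <- det$radius[m]
  grDevices::png(path, width = w, height = h)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(0, w), ylim = c(h, 0), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  graphics::rasterImage(image@pixels / fullScale(image), 0, h, w, 0)
  col_for <- function(role, flag) {
    if (flag == "invalid") "red"
    else if (role != "sample") "green"
    else if (flag == "in_range") "white"
    else "orange"
  }
  theta <- seq(0, 2 * pi, length.out = 60)
  for (i in seq_len(nrow(wells))) {
    if (is.na(cx[i])) next
    cc <- col_for(wells$role[i], wells$flag[i])
    graphics::lines(cx[i] + rad[i] * cos(theta), cy[i] + rad[i] * sin(theta),
                    col = cc, lwd = 2)
    lab <- if (wells$role[i] == "sample" && is.finite(wells$conc_mM[i]))
      sprintf("%.2f mM", wells$conc_mM[i]) else wells$label[i]
    if (nzchar(lab))
      graphics::text(cx[i], cy[i] + rad[i] + 8, lab, col = cc, cex = 0.7)
  }
  invisible(path)
}
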