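#' Fit the linear ratio-versus-concentration calibration
#'
#' Ordinary least squares of the green/red ratio on cadmium concentration over
#' the plate's calibration wells (the 0 mM water control anchors the
#' intercept, the pure-green ratio). Replicate standards at the same
#' concentration enter individually. A non-negative fitted slope is rejected:
#' the assay's color shift requires the ratio to fall with cadmium, so a flat
#' or rising line signals assay failure or mislabelled wells.
#'
#' @param concentration numeric vector of standard concentrations (mM, >= 0).
#' @param ratio numeric vector of measured green/red ratios, same length.
#' @return A [CalibrationModel-class].
#' @examples
#' conc <- c(0, 0.1, 0.25, 0.5, 0.6, 0.8, 1.0, 1.5, 2)
#' fitCalibration(conc, 2.0 - 0.75 * conc)
#' @export
fitCalibration <- function(concentration, ratio) {
  ok <- is.finite(concentration) & is.finite(ratio)
  concentration <- concentration[ok]; ratio <- ratio[ok]
  n <- length(concentration)
  if (n < 3L || length(unique(concentration)) < 2L)
    clStop("cadmilume_insufficient_calibration_error",
           sprintf("calibration needs >= 3 points at >= 2 concentrations (got %d)", n))
  if (any(concentration < 0))
    clStop("cadmilume_input_error", "standard concentrations must be >= 0 mM")
  fit <- stats::lm(ratio ~ concentration)
  beta <- stats::coef(fit)
  if (!is.finite(beta[2]) || beta[2] >= 0)
    clStop("cadmilume_non_monotone_calibration_error",
           sprintf("calibration slope %.4g per mM is not negative: the ratio must decrease with cadmium",
                   beta[2]),
           beta1 = unname(beta[2]))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((ratio - mean(ratio))^2)
  new("CalibrationModel",
      beta0 = unname(beta[1]), beta1 = unname(beta[2]),
      rSquared = if (sst > 0) max(0, min(1, 1 - sse / sst)) else 1,
      residualSD = sqrt(sse / (n - 2)),
      nPoints = as.integer(n),
      concRange = range(concentration),
      meanRatio = mean(ratio),
      sxx = sum((concentration - mean(concentration))^2))
}

#' @rdname CalibrationModel-class
#' @param object a `CalibrationModel`.
#' @export
setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    paste0("CalibrationModel: ratio = %.4f %+.4f * C (mM), n = %d, ",
           "R^2 = %.4f, residual sd = %.4g, range [%.2f, %.2f] mM\n"),
    object@beta0, object@beta1, object@nPoints, object@rSquared,
    object@residualSD, object@concRange[1], object@concRange[2]))
})

#' Estimate cadmium concentration from a measured ratio
#'
#' Inverts the calibration line, `C = (ratio - beta0) / beta1`, and attaches
#' the classical inverse-prediction (delta-method) standard error
#' `(s/|beta1|) * sqrt(1 + 1/n + (ratio - mean_ratio)^2 / (beta1^2 * sxx))`.
#' Estimates outside the standards' concentration range are flagged
#' (`below_range` / `above_range`) but still reported: clamping would hide an
#' assay failure. A non-finite ratio yields flag `invalid` with no estimate.
#'
#' @param model a [CalibrationModel-class].
#' @param ratio numeric vector of measured green/red ratios.
#' @param label character vector of well labels (recycled).
#' @return A data.frame with columns `label`, `ratio`, `concentration` (mM),
#'   `std_error` (mM), `flag` (one of `in_range`, `below_range`,
#'   `above_range`, `invalid`).
#' @export
predictConcentration <- function(model, ratio, label = "") {
  label <- rep_len(as.character(label), length(ratio))
  conc <- (ratio - model@beta0) / model@beta1
  se <- (model@residualSD / abs(model@beta1)) *
    sqrt(1 + 1 / model@nPoints +
           (ratio - model@meanRatio)^2 / (model@beta1^2 * model@sxx))
  flag <- ifelse(conc < model@concRange[1], "below_range",
                 ifelse(conc > model@concRange[2], "above_range", "in_range"))
  bad <- !is.finite(ratio)
  conc[bad] <- NA_real_; se[bad] <- NA_real_; flag[bad] <- "invalid"
  data.frame(label = label, ratio = ratio, concentration = conc,
             std_error = se, flag = flag, stringsAsFactors = FALSE)
}

#' Convert in-well estimates back to the original sample
#'
#' Dilute water samples are concentrated by evaporation before the assay;
#' dividing the in-well estimate (and its standard error) by the concentration
#' factor recovers the original sample's concentration. Values below 0.1 mM
#' are displayed in micromolar.
#'
#' @param result data.frame from [predictConcentration()].
#' @param factor fold-enrichment applied before the assay (> 0).
#' @return The result with `concentration` and `std_error` in
#'   pre-concentration mM, plus `display_value` / `display_unit` columns
#'   (`"mM"` or `"uM"`). Range flags refer to the in-well estimate and are
#'   preserved.
#' @examples
#' m <- fitCalibration(c(0, 0.5, 1, 2), 2.0 - 0.75 * c(0, 0.5, 1, 2))
#' r <- predictConcentration(m, 0.5)   # 2 mM in-well
#' applyConcentrationFactor(r, 100)    # 20 uM in the original sample
#' @export
applyConcentrationFactor <- function(result, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    clStop("cadmilume_input_error", "concentration factor must be > 0")
  result$concentration <- result$concentration / factor
  result$std_error <- result$std_error / factor
  in_uM <- !is.na(result$concentration) & abs(result$concentration) < 0.1
  result$display_value <- ifelse(in_uM, result$concentration * 1000,
                                 result$concentration)
  result$display_unit <- ifelse(in_uM, "uM", "mM")
  result
}

#' Convert millimolar cadmium to ppm (mg/L)
#'
#' `ppm = mM * molar mass (g/mol)`. The default basis is cadmium sulfate
#' (208.47 g/mol), the salt the standards are made from; elemental cadmium
#' (112.41 g/mol) is available via `basis = "cd"`.
#'
#' @param concentration_mM numeric, concentration in mM (>= 0).
#' @param basis `"cdso4"` (default) or `"cd"`.
#' @param molar_mass optional explicit molar mass in g/mol, overriding `basis`.
#' @return ppm (mg/L).
#' @examples
#' mmToPpm(2.0)            # ~417 ppm CdSO4
#' mmToPpm(0.1, "cd")      # 11.241 ppm elemental Cd
#' @export
mmToPpm <- function(concentration_mM, basis = c("cdso4", "cd"),
                    molar_mass = NULL) {
  if (is.null(molar_mass)) {
    basis <- match.arg(basis)
    molar_mass <- c(cdso4 = 208.47, cd = 112.41)[[basis]]
  }
  if (any(concentration_mM < 0, na.rm = TRUE) || molar_mass <= 0)
    clStop("cadmilume_input_error",
           "concentration must be >= 0 and molar mass > 0")
  concentration_mM * molar_mass
}

#' Save or load a calibration as JSON
#'
#' Allows calibrating once and quantifying later images against the stored
#' line.
#'
#' @param model a [CalibrationModel-class].
#' @param path JSON file path.
#' @return `exportCalibration`: `path`, invisibly. `importCalibration`: a
#'   [CalibrationModel-class].
#' @export
exportCalibration <- function(model, path) {
  jsonlite::write_json(
    list(beta0 = model@beta0, beta1 = model@beta1,
         r_squared = model@rSquared, residual_sd = model@residualSD,
         n_points = model@nPoints, conc_range = model@concRange,
         mean_ratio = model@meanRatio, sxx = model@sxx),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportCalibration
#' @export
importCalibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("CalibrationModel", beta0 = j$beta0, beta1 = j$beta1,
      rSquared = j$r_squared, residualSD = j$residual_sd,
      nPoints = as.integer(j$n_points), concRange = as.numeric(j$conc_range),
      meanRatio = j$mean_ratio, sxx = j$sxx)
}
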