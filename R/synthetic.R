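#' Construct an EmissionModel
#'
#' Defaults represent green firefly bioluminescence (550 nm) and its
#' cadmium-induced red-shifted form (610 nm) with 30 nm peak widths; the
#' true peak wavelengths of the sensing luciferase are not pinned down here,
#' so these are nominal and configurable. The ground-truth color law is
#' `ratio(C) = ratio0 + ratioSlope * C` with defaults 2.0 and -0.75 per mM,
#' which keeps the ratio positive across the 0-2 mM calibration range.
#'
#' @param lambda_green,lambda_red peak wavelengths (nm).
#' @param sigma_peak peak width (sd, nm).
#' @param ratio0 green/red ratio at 0 mM.
#' @param ratio_slope ratio change per mM (negative).
#' @param mode `"ratio_linear"` (default) or `"spectral"`.
#' @return An [EmissionModel-class].
#' @export
EmissionModel <- function(lambda_green = 550, lambda_red = 610,
                          sigma_peak = 30, ratio0 = 2.0, ratio_slope = -0.75,
                          mode = c("ratio_linear", "spectral")) {
  new("EmissionModel", lambdaGreen = lambda_green, lambdaRed = lambda_red,
      sigmaPeak = sigma_peak, ratio0 = ratio0, ratioSlope = ratio_slope,
      mode = match.arg(mode))
}

#' @rdname EmissionModel
#' @param object an `EmissionModel`.
#' @export
setMethod("show", "EmissionModel", function(object) {
  cat(sprintf(
    "EmissionModel (%s): peaks %g/%g nm (sd %g), ratio(C) = %g %+g * C\n",
    object@mode, object@lambdaGreen, object@lambdaRed, object@sigmaPeak,
    object@ratio0, object@ratioSlope))
})

#' Ground-truth green/red ratio at a given concentration
#'
#' The generator's defining color law: `ratio = ratio0 + ratioSlope * C`.
#' This is the quantity the calibration module is meant to recover.
#'
#' @param concentration mM (>= 0), vectorized.
#' @param emission an [EmissionModel-class].
#' @return The ratio(s).
#' @examples
#' ratioCurve(c(0, 1), EmissionModel())  # 2.0, 1.25
#' @export
ratioCurve <- function(concentration, emission = EmissionModel()) {
  if (any(concentration < 0))
    clStop("cadmilume_input_error", "concentration must be >= 0 mM")
  rho <- emission@ratio0 + emission@ratioSlope * concentration
  if (any(rho <= 0))
    clStop("cadmilume_spec_error",
           "green/red ratio is non-positive at the requested concentration")
  rho
}

# Camera model shared by the spectral path: Gaussian channel sensitivities
# (peak 1) centered at 460/540/610 nm with 30 nm width, sampled on the
# 400-700 nm grid at 1 nm. Returns the 3 x n sensitivity matrix.
.cameraBands <- function(lambda) {
  centers <- c(red = 610, green = 540, blue = 460)
  t(vapply(centers, function(c0) exp(-(lambda - c0)^2 / (2 * 30^2)),
           numeric(length(lambda))))
}

.spectralGrid <- function() 400:700

# Channel responses (Riemann sums) of a unit-area Gaussian emitter.
.emitterResponse <- function(mu, sigma) {
  lambda <- .spectralGrid()
  s <- stats::dnorm(lambda, mu, sigma)
  as.numeric(.cameraBands(lambda) %*% s)  # (red, green, blue)
}

#' Two-peak emission spectrum matching the ground-truth ratio
#'
#' In spectral mode a well's emission is a mixture
#' `(1 - alpha) * Gauss(lambda_green) + alpha * Gauss(lambda_red)`; the mixing
#' weight `alpha(C)` is solved numerically (bisection via [stats::uniroot()])
#' so that the camera-integrated green/red ratio equals
#' `ratioCurve(C)` exactly. As cadmium grows, alpha grows and the spectrum
#' shifts green to orange.
#'
#' @param concentration mM (scalar).
#' @param emission an [EmissionModel-class].
#' @return A data.frame (`wavelength` nm on a 1 nm 400-700 grid, `intensity`)
#'   with attribute `alpha`, the red-peak mixing weight in `[0, 1]`.
#' @export
emissionSpectrum <- function(concentration, emission = EmissionModel()) {
  target <- ratioCurve(concentration, emission)
  gr <- .emitterResponse(emission@lambdaGreen, emission@sigmaPeak)
  rd <- .emitterResponse(emission@lambdaRed, emission@sigmaPeak)
  ratio_at <- function(a) {
    mix <- (1 - a) * gr + a * rd
    mix[2] / mix[1]
  }
  lo <- ratio_at(1); hi <- ratio_at(0)
  if (target > hi + 1e-12 || target < lo - 1e-12)
    clStop("cadmilume_spec_error",
           sprintf("target ratio %.4g outside the camera gamut [%.4g, %.4g] for these peaks",
                   target, lo, hi))
  alpha <- if (target >= hi) 0 else if (target <= lo) 1 else
    stats::uniroot(function(a) ratio_at(a) - target, c(0, 1),
                   tol = 1e-13)$root
  lambda <- .spectralGrid()
  spec <- (1 - alpha) * stats::dnorm(lambda, emission@lambdaGreen, emission@sigmaPeak) +
    alpha * stats::dnorm(lambda, emission@lambdaRed, emission@sigmaPeak)
  out <- data.frame(wavelength = lambda, intensity = spec)
  attr(out, "alpha") <- alpha
  out
}

#' Noiseless RGB counts for a well at a given concentration
#'
#' The analytic oracle behind the renderer. In `ratio_linear` mode the
#' channels are set directly from the color law: `R = exposure`,
#' `G = exposure * ratio(C)`, `B = 0.1 * exposure` (a fixed blue floor). In
#' `spectral` mode each channel is `exposure` times the 1 nm Riemann sum of
#' the mixture spectrum against that channel's Gaussian sensitivity. In both
#' modes `G/R` equals `ratioCurve(C)` to within 1e-6 relative.
#'
#' @param concentration mM (scalar).
#' @param spec a [SyntheticPlateSpec-class].
#' @return Numeric length-3 `(R, G, B)` in counts.
#' @export
expectedRGB <- function(concentration, spec) {
  rho <- ratioCurve(concentration, spec@emission)
  if (spec@emission@mode == "ratio_linear") {
    spec@exposure * c(1, rho, 0.1)
  } else {
    sp <- emissionSpectrum(concentration, spec@emission)
    resp <- as.numeric(.cameraBands(sp$wavelength) %*% sp$intensity)
    spec@exposure * c(resp[1], resp[2], resp[3])
  }
}

# Rotated, unjittered well centers for all non-empty cells, aligned with
# nonEmptyCells(spec@layout). Rotation is about the image center.
.wellCenters <- function(spec) {
  cells <- nonEmptyCells(spec@layout)
  x0 <- spec@origin[1] + cells$grid_col * spec@pitch
  y0 <- spec@origin[2] + cells$grid_row * spec@pitch
  cx <- (spec@imageWidth - 1) / 2
  cy <- (spec@imageHeight - 1) / 2
  th <- spec@rotation * pi / 180
  data.frame(
    x = cx + (x0 - cx) * cos(th) - (y0 - cy) * sin(th),
    y = cy + (x0 - cx) * sin(th) + (y0 - cy) * cos(th))
}

#' Construct a SyntheticPlateSpec
#'
#' The defaults emulate the assay's bench conditions: the default layout's
#' control + 8 standards in the top row and three unknown samples at 0.5,
#' 1.0 and 1.5 mM below; 18 px wells on a 60 px pitch; exposure chosen so the
#' brightest noiseless channel peaks near 180 counts (70% of the 8-bit scale,
#' safely below saturation); a CCD noise model of Poisson photon noise plus
#' 2-count Gaussian read noise over a 5-count dark floor; 1 px well-center
#' jitter.
#'
#' @param layout a [PlateLayout-class].
#' @param sample_conc true concentrations (mM) for the layout's sample wells,
#'   in grid order.
#' @param emission an [EmissionModel-class].
#' @param exposure red-channel counts per unit emission (default 90).
#' @param well_radius,pitch well radius and grid pitch (px).
#' @param origin numeric `(x, y)` of the top-left well center (px).
#' @param rotation plate rotation (degrees).
#' @param jitter_sd well-center jitter sd (px).
#' @param photon_gain counts per photon-equivalent (0 disables photon noise).
#' @param read_sd Gaussian read noise sd (counts).
#' @param background_level dark floor (counts).
#' @param width,height image size (px).
#' @param bit_depth 8 or 16.
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   render.
#' @return A [SyntheticPlateSpec-class].
#' @export
plateSpec <- function(layout = defaultLayout(),
                      sample_conc = c(0.5, 1.0, 1.5),
                      emission = EmissionModel(),
                      exposure = 90, well_radius = 18, pitch = 60,
                      origin = c(70, 70), rotation = 0, jitter_sd = 1,
                      photon_gain = 1, read_sd = 2, background_level = 5,
                      width = 640L, height = 240L, bit_depth = 8L,
                      seed = 1L) {
  conc <- layout@conc
  is_sample <- layout@roles == "sample"
  n_samp <- sum(is_sample)
  if (length(sample_conc) != n_samp)
    clStop("cadmilume_spec_error",
           sprintf("layout has %d sample wells but %d sample concentrations were given",
                   n_samp, length(sample_conc)))
  # fill samples in row-major grid order
  ord <- which(t(is_sample))
  conc_t <- t(conc)
  conc_t[ord] <- sample_conc
  conc <- t(conc_t)
  new("SyntheticPlateSpec", layout = layout, concentrations = conc,
      emission = emission, exposure = exposure, wellRadius = well_radius,
      pitch = pitch, origin = origin, rotation = rotation,
      jitterSD = jitter_sd, photonGain = photon_gain, readSD = read_sd,
      backgroundLevel = background_level, imageWidth = as.integer(width),
      imageHeight = as.integer(height), bitDepth = as.integer(bit_depth),
      seed = as.integer(seed))
}

#' @rdname plateSpec
#' @param object a `SyntheticPlateSpec`.
#' @export
setMethod("show", "SyntheticPlateSpec", function(object) {
  cells <- nonEmptyCells(object@layout)
  cat(sprintf(
    paste0("SyntheticPlateSpec: %d wells, %dx%d px %d-bit, r = %g px, ",
           "pitch %g px, rotation %g deg, seed %d (%s mode)\n"),
    nrow(cells), object@imageWidth, object@imageHeight, object@bitDepth,
    object@wellRadius, object@pitch, object@rotation, object@seed,
    object@emission@mode))
})

# Radial well profile: flat core to 0.8 r, cosine falloff to the rim.
.radialProfile <- function(d, r) {
  ifelse(d <= 0.8 * r, 1,
         ifelse(d <= r, 0.5 * (1 + cos(pi * (d - 0.8 * r) / (0.2 * r))), 0))
}

#' Render a synthetic plate photograph with ground truth
#'
#' Draws each well as a disk (flat core, cosine rim) scaled by its noiseless
#' [expectedRGB()] over a uniform dark floor, then applies per-pixel Poisson
#' photon noise (through `photon_gain`) and Gaussian read noise, quantizes,
#' and clips to the bit depth. All randomness (center jitter and noise) comes
#' from one generator seeded with `spec@seed`, so the same spec renders
#' bit-identically.
#'
#' @param spec a [SyntheticPlateSpec-class].
#' @param noise logical; `FALSE` renders the noiseless mean image (still
#'   quantized).
#' @return A list: `image` (a [PlateImage-class]) and `truth`, a data.frame
#'   with one row per well: `grid_row`, `grid_col`, `role`, `label`,
#'   `conc_mM`, `true_ratio`, `R0`, `G0`, `B0` (noiseless counts) and the
#'   jittered `center_x`, `center_y`.
#' @export
renderPlate <- function(spec, noise = TRUE) {
  cells <- nonEmptyCells(spec@layout)
  ctr <- .wellCenters(spec)
  n <- nrow(cells)
  h <- spec@imageHeight; w <- spec@imageWidth
  conc <- spec@concentrations[cbind(cells$grid_row + 1L, cells$grid_col + 1L)]
  rgb0 <- t(vapply(conc, expectedRGB, numeric(3), spec = spec))
  full <- 2^spec@bitDepth - 1
  res <- withr::with_seed(spec@seed, {
    cx <- ctr$x + stats::rnorm(n, 0, spec@jitterSD)
    cy <- ctr$y + stats::rnorm(n, 0, spec@jitterSD)
    mean_img <- array(spec@backgroundLevel, c(h, w, 3))
    for (k in seq_len(n)) {
      box <- .diskBox(h, w, cx[k], cy[k], spec@wellRadius)
      prof <- .radialProfile(box$d, spec@wellRadius)
      for (ch in 1:3) {
        mean_img[box$rows, box$cols, ch] <-
          mean_img[box$rows, box$cols, ch] + prof * rgb0[k, ch]
      }
    }
    counts <- if (noise) {
      shot <- if (spec@photonGain > 0) {
        spec@photonGain * stats::rpois(length(mean_img),
                                       mean_img / spec@photonGain)
      } else as.numeric(mean_img)
      shot + stats::rnorm(length(mean_img), 0, spec@readSD)
    } else as.numeric(mean_img)
    list(counts = array(counts, dim(mean_img)), cx = cx, cy = cy)
  }, .rng_kind = "Mersenne-Twister")
  px <- pmin(pmax(round(res$counts), 0), full)
  truth <- data.frame(cells[c("grid_row", "grid_col", "role", "label")],
                      conc_mM = conc,
                      true_ratio = ratioCurve(conc, spec@emission),
                      R0 = rgb0[, 1], G0 = rgb0[, 2], B0 = rgb0[, 3],
                      center_x = res$cx, center_y = res$cy)
  list(image = PlateImage(px, spec@bitDepth), truth = truth)
}
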