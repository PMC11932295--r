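standards <- c(0, 0.1, 0.25, 0.5, 0.6, 0.8, 1.0, 1.5, 2)

test_that("exact points on a line are fitted exactly", {
  m <- fitCalibration(standards, 2.0 - 0.75 * standards)
  expect_equal(m@beta0, 2.0, tolerance = 1e-12)
  expect_equal(m@beta1, -0.75, tolerance = 1e-12)
  expect_equal(m@rSquared, 1, tolerance = 1e-12)
  expect_equal(m@residualSD, 0, tolerance = 1e-9)
  expect_equal(m@nPoints, 9L)
  expect_equal(m@concRange, c(0, 2))
  expect_equal(m@sxx, sum((standards - mean(standards))^2))
})

test_that("OLS matches a brute-force SSE grid minimizer", {
  set.seed(3)
  for (i in 1:5) {
    conc <- c(0, 0.5, 1, 1.5, 2)
    rho <- 2.1 - 0.8 * conc + rnorm(5, 0, 0.05)
    m <- fitCalibration(conc, rho)
    b0g <- seq(m@beta0 - 0.1, m@beta0 + 0.1, length.out = 81)
    b1g <- seq(m@beta1 - 0.1, m@beta1 + 0.1, length.out = 81)
    sse <- outer(b0g, b1g, Vectorize(function(b0, b1)
      sum((rho - b0 - b1 * conc)^2)))
    best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    step <- 0.2 / 80
    expect_lt(abs(b0g[best[1]] - m@beta0), step)
    expect_lt(abs(b1g[best[2]] - m@beta1), step)
    expect_lte(sum((rho - m@beta0 - m@beta1 * conc)^2), min(sse) + 1e-12)
  }
})

test_that("noisy fits land within 3 analytic standard errors", {
  sigma <- 0.02
  n <- length(standards)
  sxx <- sum((standards - mean(standards))^2)
  se1 <- sigma / sqrt(sxx)
  se0 <- sigma * sqrt(1 / n + mean(standards)^2 / sxx)
  set.seed(42)
  hits <- 0
  for (i in 1:1000) {
    rho <- 2.0 - 0.75 * standards + rnorm(n, 0, sigma)
    m <- fitCalibration(standards, rho)
    if (abs(m@beta0 - 2.0) <= 3 * se0 && abs(m@beta1 + 0.75) <= 3 * se1)
      hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.99)
})

test_that("degenerate calibrations are rejected with diagnostic errors", {
  expect_error(fitCalibration(c(0, 1), c(2, 1.25)),
               class = "cadmilume_insufficient_calibration_error")
  expect_error(fitCalibration(c(1, 1, 1), c(2, 1.9, 2.1)),
               class = "cadmilume_insufficient_calibration_error")
  expect_error(fitCalibration(c(0, 1, 2), c(1, 1.5, 2)),
               class = "cadmilume_non_monotone_calibration_error")
})

test_that("inverse prediction inverts the line with range flags", {
  m <- fitCalibration(standards, 2.0 - 0.75 * standards)
  p <- predictConcentration(m, 1.25)
  expect_equal(p$concentration, 1.0, tolerance = 1e-12)
  expect_equal(p$flag, "in_range")
  p_lo <- predictConcentration(m, 2.15)
  expect_equal(p_lo$concentration, -0.2, tolerance = 1e-12)
  expect_equal(p_lo$flag, "below_range")
  p_hi <- predictConcentration(m, 0.125)
  expect_equal(p_hi$concentration, 2.5, tolerance = 1e-12)
  expect_equal(p_hi$flag, "above_range")
  p_bad <- predictConcentration(m, NaN)
  expect_equal(p_bad$flag, "invalid")
  expect_true(is.na(p_bad$concentration))
})

test_that("round trip and monotonicity hold for random valid models", {
  set.seed(8)
  for (i in 1:30) {
    conc <- sort(runif(6, 0, 2))
    b0 <- runif(1, 1.5, 2.5); b1 <- -runif(1, 0.3, 0.9)
    m <- fitCalibration(conc, b0 + b1 * conc + rnorm(6, 0, 0.01))
    cs <- runif(5, 0, 2)
    back <- predictConcentration(m, m@beta0 + m@beta1 * cs)$concentration
    expect_equal(back, cs, tolerance = 1e-9)
    rhos <- seq(0.3, 2.2, length.out = 7)
    est <- predictConcentration(m, rhos)$concentration
    expect_true(all(diff(est) < 0))  # decreasing in the ratio
  }
})

test_that("inverse-prediction uncertainty is smallest at the mean ratio", {
  set.seed(13)
  m <- fitCalibration(standards, 2.0 - 0.75 * standards + rnorm(9, 0, 0.02))
  d <- c(0.1, 0.3, 0.6)
  se_up <- predictConcentration(m, m@meanRatio + d)$std_error
  se_dn <- predictConcentration(m, m@meanRatio - d)$std_error
  se_mid <- predictConcentration(m, m@meanRatio)$std_error
  expect_equal(se_up, se_dn, tolerance = 1e-12)   # symmetric
  expect_true(all(diff(se_up) > 0))               # grows away from the mean
  expect_true(all(se_up > se_mid))
  expect_equal(se_mid,
               m@residualSD / abs(m@beta1) * sqrt(1 + 1 / m@nPoints),
               tolerance = 1e-12)
})

test_that("concentration-factor correction recovers original sample units", {
  m <- fitCalibration(standards, 2.0 - 0.75 * standards)
  r <- predictConcentration(m, 0.5)   # 2.0 mM in the well
  expect_equal(r$concentration, 2.0, tolerance = 1e-12)
  back <- applyConcentrationFactor(r, 100)
  expect_equal(back$concentration, 0.02, tolerance = 1e-12)  # 20 uM original
  expect_equal(back$display_value, 20, tolerance = 1e-12)
  expect_equal(back$display_unit, "uM")
  ident <- applyConcentrationFactor(r, 1)
  expect_equal(ident$concentration, r$concentration)
  expect_equal(ident$display_unit, "mM")
  expect_error(applyConcentrationFactor(r, 0),
               class = "cadmilume_input_error")
})

test_that("millimolar converts to ppm on the chosen molar-mass basis", {
  expect_equal(mmToPpm(0), 0)
  expect_equal(mmToPpm(2.0), 416.94)
  expect_equal(mmToPpm(0.1, basis = "cd"), 11.241)
  expect_error(mmToPpm(-1), class = "cadmilume_input_error")
})

test_that("calibrations survive a JSON round trip", {
  set.seed(2)
  m <- fitCalibration(standards, 2.0 - 0.75 * standards + rnorm(9, 0, 0.02))
  f <- withr::local_tempfile(fileext = ".json")
  exportCalibration(m, f)
  m2 <- importCalibration(f)
  for (sl in c("beta0", "beta1", "rSquared", "residualSD", "meanRatio", "sxx"))
    expect_equal(slot(m2, sl), slot(m, sl), tolerance = 1e-12)
  expect_equal(predictConcentration(m2, 1.1), predictConcentration(m, 1.1))
})
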