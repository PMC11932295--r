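test_that("detection channel is the per-pixel channel maximum", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(10, 200, 30)
  px[1, 2, ] <- c(100, 100, 100)
  ch <- detectionChannel(PlateImage(px))
  expect_equal(ch[1, 1], 200)
  expect_equal(ch[1, 2], 100)
  expect_equal(ch[2, 1], 0)
  expect_true(all(detectionChannel(makeImage(5, 5)) == 0))
  expect_error(PlateImage(matrix(0, 4, 4)), class = "cadmilume_input_error")
})

test_that("Otsu threshold separates a two-level image exactly and matches an independent implementation", {
  ch <- matrix(10, 40, 40)
  ch[10:20, 10:20] <- 200
  bin <- binarizeImage(ch, opening_radius = 0)
  expect_identical(bin$mask, ch == 200)
  expect_true(bin$threshold >= 10 && bin$threshold < 200)
  # constant image has no separable classes
  expect_error(binarizeImage(matrix(7, 10, 10)),
               class = "cadmilume_degenerate_histogram_error")
  # cross-check against EBImage's Otsu on bimodal histograms (bin-center
  # conventions differ by at most one grey level)
  set.seed(11)
  for (i in 1:6) {
    v <- pmin(pmax(round(c(rnorm(4000, 40, 12), rnorm(1200, 170, 20))), 0), 255)
    m <- matrix(v, 80, 65)
    mine <- otsuThreshold(m, 256)
    eb <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1),
                        levels = 256) * 255
    expect_lt(abs(mine - eb), 1)
  }
})

test_that("morphological opening removes sub-structuring-element specks", {
  ch <- matrix(0, 30, 30)
  ch[10:20, 10:20] <- 200  # survives
  ch[3, 4:5] <- 200        # 2-pixel speck, erased by radius-1 opening
  bin <- binarizeImage(ch, opening_radius = 1)
  expect_false(any(bin$mask[1:5, 1:8]))
  expect_true(all(bin$mask[12:18, 12:18]))
})

test_that("well detection recovers disk centroid, radius and circularity", {
  expect_equal(nrow(detectWells(matrix(FALSE, 20, 20))), 0)

  mask <- diskMask(120, 130, 60, 50, 20)
  det <- detectWells(mask)
  expect_equal(nrow(det), 1)
  # oracle: centroid and area from the disk's own pixel set
  idx <- which(mask, arr.ind = TRUE)
  expect_equal(det$center_x, mean(idx[, 2]) - 1, tolerance = 1e-12)
  expect_equal(det$center_y, mean(idx[, 1]) - 1, tolerance = 1e-12)
  expect_lt(abs(det$center_x - 60), 1)
  expect_lt(abs(det$center_y - 50), 1)
  expect_equal(det$area, nrow(idx))
  expect_lt(abs(det$radius - 20) / 20, 0.05)
  expect_gt(det$circularity, 0.9)
  expect_lte(det$circularity, 1)

  # speck below min_area is discarded
  mask2 <- mask
  mask2[5, 5:9] <- TRUE
  expect_equal(nrow(detectWells(mask2, min_area = 100)), 1)

  # elongated streak fails the circularity filter
  streak <- matrix(FALSE, 60, 200)
  streak[28:32, 20:180] <- TRUE
  expect_equal(nrow(detectWells(streak, min_area = 100)), 0)
})

test_that("detected centers are translation-equivariant", {
  base <- diskMask(100, 100, 40, 45, 12) | diskMask(100, 100, 75, 30, 10)
  d0 <- detectWells(base)
  for (shift in list(c(3, 7), c(-5, 4), c(10, -8))) {
    h <- 100; w <- 100
    shifted <- matrix(FALSE, h, w)
    src <- which(base, arr.ind = TRUE)
    dst <- cbind(src[, 1] + shift[2], src[, 2] + shift[1])
    keep <- dst[, 1] >= 1 & dst[, 1] <= h & dst[, 2] >= 1 & dst[, 2] <= w
    shifted[dst[keep, , drop = FALSE]] <- TRUE
    d1 <- detectWells(shifted)
    expect_equal(d1$center_x, d0$center_x + shift[1], tolerance = 1e-9)
    expect_equal(d1$center_y, d0$center_y + shift[2], tolerance = 1e-9)
  }
})

test_that("grid assignment maps a 9-over-4 scene to standards and samples", {
  layout <- defaultLayout(sample_labels = c("S1", "S2", "S3", "S4"))
  cx <- c(70 + 60 * (0:8), 70 + 60 * (0:3))
  cy <- c(rep(70, 9), rep(130, 4))
  det <- assignGrid(fakeDetections(cx, cy, 18), layout)
  expect_equal(det$grid_row, c(rep(0L, 9), rep(1L, 4)))
  expect_equal(det$grid_col, c(0:8, 0:3))
  expect_equal(det$role, c("control", rep("standard", 8), rep("sample", 4)))
  expect_equal(det$conc_mM[2:9], c(0.1, 0.25, 0.5, 0.6, 0.8, 1.0, 1.5, 2.0))
  expect_equal(det$label[10:13], c("S1", "S2", "S3", "S4"))
  # bijection onto non-empty cells
  expect_equal(nrow(unique(det[c("grid_row", "grid_col")])), 13)
})

test_that("grid assignment is invariant to a 3-degree plate rotation", {
  layout <- defaultLayout(sample_labels = c("S1", "S2", "S3", "S4"))
  cx <- c(70 + 60 * (0:8), 70 + 60 * (0:3))
  cy <- c(rep(70, 9), rep(130, 4))
  th <- 3 * pi / 180
  ctr <- c(319.5, 119.5)
  rx <- ctr[1] + (cx - ctr[1]) * cos(th) - (cy - ctr[2]) * sin(th)
  ry <- ctr[2] + (cx - ctr[1]) * sin(th) + (cy - ctr[2]) * cos(th)
  d0 <- assignGrid(fakeDetections(cx, cy, 18), layout)
  d1 <- assignGrid(fakeDetections(rx, ry, 18), layout)
  key0 <- order(d0$grid_row, d0$grid_col)
  expect_equal(d1$grid_row, d0$grid_row)
  expect_equal(d1$grid_col, d0$grid_col)
  expect_equal(d1$role, d0$role)
})

test_that("grid assignment errors are specific", {
  layout <- defaultLayout()
  expect_error(assignGrid(fakeDetections(c(10, 50), c(10, 10), 5), layout),
               class = "cadmilume_layout_mismatch_error")
  # right count, wrong row structure: all 12 wells in one physical row
  det <- fakeDetections(seq(10, 620, length.out = 12), rep(50, 12), 10)
  expect_error(assignGrid(det, layout),
               class = "cadmilume_grid_inference_error")
})

test_that("a single-row layout assigns from grid index (0, 0)", {
  roles <- matrix(c("control", "standard", "standard"), 1, 3)
  conc <- matrix(c(NA, 0.5, 1), 1, 3)
  layout <- PlateLayout(roles, conc)
  det <- assignGrid(fakeDetections(c(10, 40, 70), c(20, 20, 20), 5), layout)
  expect_equal(det$grid_row, c(0L, 0L, 0L))
  expect_equal(det$grid_col, 0:2)
})
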