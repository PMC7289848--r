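test_that("detection finds the bar component with correct pose", {
  img <- bar_image(20, 4, size = 60, value = 100)
  det <- detect_ring(img, threshold = 50)
  expect_s3_class(det, "ring_detection")
  expect_equal(unname(det$center["x"]), 30.5, tolerance = 0.5)
  expect_equal(unname(det$center["y"]), 30.5, tolerance = 0.5)
  expect_equal(det$orientation, 0, tolerance = 1e-9)  # along the bar
  expect_equal(det$area_px, 20 * 4)
})

test_that("absence and sub-minimum components yield no detection", {
  expect_null(detect_ring(matrix(1, 30, 30), threshold = 50))
  img <- matrix(0, 30, 30)
  img[10:12, 10:12] <- 100  # 9-px component, below the 10-px minimum
  expect_null(detect_ring(img, threshold = 50))
  img[13, 10] <- 100        # now 10 px: detected
  expect_s3_class(detect_ring(img, threshold = 50), "ring_detection")
})

test_that("profile extraction counts and averages correctly", {
  img <- matrix(0, 80, 80)
  det <- detect_ring(bar_image(20, 4, size = 80, value = 100), 50)
  prof <- extract_profile(img, det, half_length = 30)
  expect_length(prof$values, 61)
  # perpendicular averaging: column ramp 0..nrow-1 -> mean of 10 offsets
  ramp <- matrix(seq_len(80) - 1, 80, 80)  # value = y - 1
  profr <- extract_profile(ramp, det, half_length = 5, avg_width = 10)
  # the 10 perpendicular samples straddle the line at offsets -4.5..4.5;
  # on the ramp their values are center - 1 + (-4.5..4.5), so the mean is
  # the ramp value at the line itself (a 0..9 column averages to 4.5)
  expect_equal(profr$values,
               rep(unname(det$center["y"]) - 1, 11), tolerance = 1e-9)
})

test_that("profile of an axis-aligned bar has a plateau of the bar length", {
  img <- bar_image(20, 4, size = 80, value = 100)
  det <- detect_ring(img, 50)
  prof <- extract_profile(img, det)
  sub <- smooth_subtract_background(prof)
  fw <- fwhm_diameter(sub, pixel_size = 1)
  expect_true(fw$valid)
  expect_equal(fw$diameter_um, 20, tolerance = 1)
})

test_that("background subtraction uses the outer three samples per side", {
  p <- intensity_profile(1:11, c(2, 2, 2, 3, 5, 6, 5, 3, 2, 2, 2),
                         smoothed = TRUE)
  sub <- subtract_background(p)
  expect_equal(sub$values[6], 4)           # peak 6 minus background 2
  expect_equal(max(sub$values), 4)
  # constant profile maps to zeros
  const <- smooth_subtract_background(intensity_profile(1:15, rep(7, 15)))
  expect_equal(const$values, rep(0, 15))
  # additive offsets cancel
  p2 <- intensity_profile(1:11, p$values + 13)
  expect_equal(subtract_background(p2)$values, sub$values)
  expect_error(smooth_subtract_background(intensity_profile(1:5, 1:5)),
               "7 samples")
})

test_that("FWHM interpolates crossings to sub-pixel precision", {
  p <- intensity_profile(0:8, c(0, 0, 4, 4, 4, 4, 4, 0, 0),
                         background_subtracted = TRUE)
  fw <- fwhm_diameter(p, pixel_size = 0.1)
  expect_true(fw$valid)
  expect_equal(fw$left_px, 1.5)
  expect_equal(fw$right_px, 6.5)
  expect_equal(fw$diameter_um, 0.5)
})

test_that("FWHM of a Gaussian matches the closed form", {
  x <- seq(-30, 30)
  g <- intensity_profile(x, exp(-x^2 / (2 * 25)),
                         background_subtracted = TRUE)
  expect_lt(abs(fwhm_diameter(g, 1)$diameter_um -
                  2 * sqrt(2 * log(2)) * 5), 0.2)
  # with the 3-px gliding average first, a brute-force oracle on a fine
  # grid gives the widened width of the smoothed Gaussian
  fine <- seq(-30, 30, by = 0.001)
  sm_fine <- (stats::dnorm(fine, 0, 5) + stats::dnorm(fine - 1, 0, 5) +
                stats::dnorm(fine + 1, 0, 5)) / 3
  half <- max(sm_fine) / 2
  oracle <- diff(range(fine[sm_fine >= half]))
  sm <- subtract_background(smooth_profile(g))
  expect_equal(fwhm_diameter(sm, 1)$diameter_um, oracle, tolerance = 0.02)
  expect_equal(oracle, 11.9, tolerance = 0.01)
})

test_that("degenerate profiles are flagged invalid, not errors", {
  z <- intensity_profile(1:11, rep(0, 11), background_subtracted = TRUE)
  expect_false(fwhm_diameter(z, 1)$valid)
  # signal touching the profile end: no crossing on that side
  touch <- intensity_profile(1:11, c(5, 5, 5, 5, 2, 0, 0, 0, 0, 0, 0),
                             background_subtracted = TRUE)
  expect_false(fwhm_diameter(touch, 1)$valid)
})

test_that("integrated intensity sums clipped subtracted samples", {
  expect_equal(ring_total_intensity(intensity_profile(1:9, rep(0, 9))), 0)
  p <- intensity_profile(0:8, c(0, 0, 4, 4, 4, 4, 4, 0, 0))
  expect_equal(ring_total_intensity(p), 20)
  p2 <- intensity_profile(0:13, c(0, 0, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 0, 0))
  expect_equal(ring_total_intensity(p2), 40)
  # negative samples are clipped
  expect_equal(ring_total_intensity(intensity_profile(1:3, c(-1, 2, -5))), 2)
})

test_that("measured diameter is invariant to gain and offset", {
  cell <- test_cell()
  fr <- render_cell_frame(cell, render_config(read_noise_sd = 0))
  base <- measure_ring(fr$image, 200, 0.1)
  for (k in c(0.5, 2, 7)) {
    mk <- measure_ring(fr$image * k, 200 * k, 0.1)
    expect_equal(mk$d_um, base$d_um, tolerance = 1e-9)
  }
  moff <- measure_ring(fr$image + 400, 600, 0.1)
  expect_equal(moff$d_um, base$d_um, tolerance = 1e-9)
})

test_that("bar-length recovery holds across PSF widths", {
  for (len_px in c(10, 25, 40)) {
    for (sigma in c(0.5, 1, 2)) {
      cell <- test_cell(d_ring = len_px * 0.1)
      rc <- render_config(read_noise_sd = 0, psf_sigma = sigma)
      fr <- render_cell_frame(cell, rc)
      m <- measure_ring(fr$image, 200, 0.1)
      expect_true(m$valid)
      expect_lt(abs(m$d_um / 0.1 - len_px), 1)
    }
  }
})

test_that("contour-profile diameter recovers an arc of known extent", {
  # circular contour r = 2 um (20 px at 0.1 um/px), 65 vertices; a bright
  # arc spanning 10 vertex gaps -> arc length 10 * 2 pi r / 65 = 1.93 um
  ct <- circle_contour(20, 65, center = c(35, 35))
  gap <- 2 * pi / 65
  x <- matrix(seq_len(70), 70, 70, byrow = TRUE)
  y <- matrix(seq_len(70), 70, 70)
  ang <- atan2(y - 35, x - 35)
  arc <- abs(((ang + pi) %% (2 * pi)) - pi) <= 5 * gap
  img <- matrix(100, 70, 70) + 400 * arc
  res <- contour_ring_diameter(list(img, img, img, img, img), ct, 0.1)
  expect_true(res$valid)
  expect_equal(res$diameter_um, 10 * gap * 2, tolerance = 0.15)
  # circular shift of the vertex labeling leaves the diameter unchanged
  shift <- rbind(ct[30:65, ], ct[1:29, ])
  res2 <- contour_ring_diameter(list(img, img, img, img, img), shift, 0.1)
  expect_equal(res2$diameter_um, res$diameter_um, tolerance = 1e-9)
  # flat profile is invalid
  flat <- contour_ring_diameter(list(matrix(5, 70, 70)), ct, 0.1)
  expect_false(flat$valid)
})
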