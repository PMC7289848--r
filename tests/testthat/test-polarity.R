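test_that("cluster threshold is median + 2 population SD of in-mask pixels", {
  # mixture: 900 px at 100 a.u. + 100 px at 1000 a.u. inside the mask
  img <- matrix(0, 40, 40)
  m <- matrix(FALSE, 40, 40)
  m[1:25, 1:40] <- TRUE          # 1000 in-mask pixels
  img[m] <- 100
  img[1:4, 1:25] <- 1000         # 100 of them bright
  expect_equal(cluster_threshold(img, m), 640)
  # out-of-mask pixels are ignored
  img2 <- img; img2[!m] <- 1e6
  expect_equal(cluster_threshold(img2, m), 640)
  # uniform intensity: threshold equals the value, strictly-above rule
  # leaves the cluster empty
  u <- matrix(50, 10, 10)
  expect_equal(cluster_threshold(u, matrix(TRUE, 10, 10) & row(u) < 9), 50)
  expect_equal(sum(ringscale:::cluster_pixels(u, row(u) < 9)), 0)
  expect_error(cluster_threshold(img, matrix(FALSE, 40, 40)), "empty")
})

test_that("cluster area is the median pixel count over three frames", {
  m <- matrix(TRUE, 30, 30); m[30, ] <- FALSE
  mk_frame <- function(n_bright) {
    img <- matrix(100, 30, 30)
    img[seq_len(n_bright)] <- 5000
    img
  }
  # per-frame counts 8, 10, 14 -> median 10 px; at 0.1 um/px -> 0.10 um2
  res <- cluster_area(list(mk_frame(8), mk_frame(10), mk_frame(14)), m, 0.1)
  expect_true(res$valid)
  expect_equal(res$n_px, 10)
  expect_equal(res$area_um2, 0.10)
  # all-background frames: invalid, not an error
  flat <- matrix(100, 30, 30)
  res2 <- cluster_area(list(flat, flat, flat), m, 0.1)
  expect_false(res2$valid)
})

test_that("cluster axes use the moment convention on the largest object", {
  cl <- matrix(FALSE, 30, 30)
  cl[11:14, 6:15] <- TRUE        # 10 x 4 solid rectangle
  ax <- cluster_axes(cl, pixel_size = 1)
  expect_equal(ax$major_um, 4 * sqrt(100 / 12), tolerance = 1e-9)  # 11.55
  expect_equal(ax$minor_um, 4 * sqrt(16 / 12), tolerance = 1e-9)   # 4.62
  # a smaller disconnected blob does not change the axes
  cl2 <- cl; cl2[25:27, 25:27] <- TRUE
  ax2 <- cluster_axes(cl2, pixel_size = 1)
  expect_equal(ax2$major_um, ax$major_um)
  expect_equal(ax2$minor_um, ax$minor_um)
  # a disk has equal axes
  axd <- cluster_axes(disk_mask(8), pixel_size = 1)
  expect_lt(abs(axd$major_um / axd$minor_um - 1), 0.02)
  expect_false(cluster_axes(matrix(FALSE, 5, 5), 1)$valid)
})

test_that("contour cluster length recovers an arc of known extent", {
  ct <- circle_contour(20, 65, center = c(35, 35))
  gap <- 2 * pi / 65
  x <- matrix(seq_len(70), 70, 70, byrow = TRUE)
  y <- matrix(seq_len(70), 70, 70)
  ang <- atan2(y - 35, x - 35)
  arc <- abs(((ang + pi) %% (2 * pi)) - pi) <= 5 * gap
  rad2 <- (x - 35)^2 + (y - 35)^2
  shell <- rad2 >= 16^2 & rad2 <= 21^2
  img <- matrix(100, 70, 70) + 800 * (arc & shell)
  m <- disk_mask(21, size = 70)
  res <- cluster_contour_length(list(img, img, img), ct, m, 0.1)
  expect_true(res$valid)
  # independent arc-length oracle: angular extent where the 5 x 5
  # max-filtered image at the contour radius exceeds the threshold
  thr <- cluster_threshold(img, m)
  mf <- ringscale:::max_filter(img, 5L)
  phi <- seq(-pi, pi, length.out = 20001)
  on <- mf[cbind(round(35 + 20 * sin(phi)),
                 round(35 + 20 * cos(phi)))] > thr
  oracle_um <- mean(on) * 2 * pi * 2  # fraction of the r = 2 um perimeter
  expect_lt(abs(res$length_um - oracle_um), 0.15)
  # the max filter widens the run slightly, so the geometric arc length of
  # the painted region (10 gaps = 1.93 um) is recovered only approximately
  expect_lt(abs(res$length_um - 10 * gap * 2), 0.6)
  # circular shift of vertex labels leaves the length unchanged
  shift <- rbind(ct[20:65, ], ct[1:19, ])
  res2 <- cluster_contour_length(list(img, img, img), shift, m, 0.1)
  expect_equal(res2$length_um, res$length_um, tolerance = 1e-9)
  # nothing above threshold: invalid
  resf <- cluster_contour_length(list(matrix(100, 70, 70)), ct, m, 0.1)
  expect_false(resf$valid)
})

test_that("cluster threshold and membership behave under intensity maps", {
  img <- matrix(100, 30, 30)
  img[10:13, 10:13] <- 900
  m <- matrix(TRUE, 30, 30); m[1, ] <- FALSE
  thr <- cluster_threshold(img, m)
  expect_equal(cluster_threshold(img * 3, m), 3 * thr, tolerance = 1e-9)
  # affine positive-gain maps leave membership unchanged
  base <- ringscale:::cluster_pixels(img, m)
  expect_identical(ringscale:::cluster_pixels(img * 3 + 40, m), base)
})

test_that("circle fit is exact, noise-robust and rigid-motion invariant", {
  ct <- circle_contour(2, 65, center = c(5, 7))
  r <- local_curvature_radius(ct, anchor = 10, window = 7, pixel_size = 1)
  expect_equal(r$radius_um, 2, tolerance = 1e-9)
  expect_lt(r$residual_um, 1e-9)
  # rigid motions: rotation + translation leave the radius unchanged
  th <- 0.7
  rot <- cbind(ct[, 1] * cos(th) - ct[, 2] * sin(th) + 3,
               ct[, 1] * sin(th) + ct[, 2] * cos(th) - 11)
  r2 <- local_curvature_radius(rot, anchor = 10, window = 7, pixel_size = 1)
  expect_equal(r2$radius_um, r$radius_um, tolerance = 1e-9)
  # vertex noise sigma = 0.01 um on 7 vertices of an r = 2 um circle:
  # median fitted radius within 2% of truth over 100 trials
  ct7 <- circle_contour(2, 7)
  set.seed(99)
  errs <- replicate(100, {
    noisy <- ct7 + matrix(rnorm(14, 0, 0.01), ncol = 2)
    local_curvature_radius(noisy, anchor = 4, window = 7,
                           pixel_size = 1)$radius_um
  })
  expect_lt(abs(median(errs) / 2 - 1), 0.02)
  # collinear vertices are degenerate
  line <- cbind(1:7, 2 * (1:7) + 1)
  expect_error(local_curvature_radius(line, anchor = 4, window = 7),
               "collinear")
})

test_that("median curvature over frames matches the generating geometry", {
  # pole of a prolate spheroid: radius of curvature b^2 / a
  cell <- test_cell(orientation = 0.2)
  fr <- render_cell_frame(cell, render_config(read_noise_sd = 0))
  ct <- resample_contour(fr$mask$contour, 65)
  # anchor at the pole: vertex closest to the pole point
  px <- cell$pixel_size
  n <- nrow(fr$image)
  pole <- c((n + 1) / 2 + cell$semi_major_um / px * cos(cell$orientation),
            (n + 1) / 2 + cell$semi_major_um / px * sin(cell$orientation))
  anchor <- which.min((ct[, 1] - pole[1])^2 + (ct[, 2] - pole[2])^2)
  rad <- median_curvature_radius(rep(list(ct), 5), anchor, pixel_size = px)
  expect_equal(rad, cell$semi_minor_um^2 / cell$semi_major_um,
               tolerance = 0.05)
})

test_that("larger rendered clusters measure as larger areas", {
  # noiseless ladder of cluster sizes rendered via the timecourse channel
  rc <- render_config(read_noise_sd = 0)
  areas <- vapply(c(0.6, 0.9, 1.2, 1.5, 1.8), function(dc) {
    cell <- test_cell(d_cluster = dc)
    tc <- generate_timecourse(cell, rc)
    pk <- tc$events$cluster_peak_frame
    imgs <- lapply((pk - 1):(pk + 1), function(f) tc$frames[[f]]$cluster)
    cluster_area(imgs, tc$frames[[pk]]$mask, cell$pixel_size)$area_um2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("cluster axis length and contour length are correlated measures", {
  # across a synthetic population with varying cluster size, the two
  # published size measures must agree (Pearson R > 0.5)
  rc <- render_config(read_noise_sd = 1)
  cells <- generate_population(population_config(n_cells = 30, seed = 17))
  res <- vapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    tc <- generate_timecourse(cell, rc, seed = 1000 + i)
    pk <- tc$events$cluster_peak_frame
    imgs <- lapply((pk - 1):(pk + 1), function(f) tc$frames[[f]]$cluster)
    msk <- tc$frames[[pk]]$mask
    cl <- ringscale:::cluster_pixels(imgs[[2]], msk$mask)
    ax <- cluster_axes(cl, cell$pixel_size)
    ct <- resample_contour(msk$contour, 65)
    len <- cluster_contour_length(imgs, ct, msk, cell$pixel_size)
    c(ax$major_um, len$length_um)
  }, numeric(2))
  keep <- is.finite(res[1, ]) & is.finite(res[2, ])
  expect_gt(sum(keep), 20)
  expect_gt(pearson_correlation(res[1, keep], res[2, keep])$R, 0.5)
})
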