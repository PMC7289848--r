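test_that("zero-noise populations satisfy the spherical closed form", {
  # with alpha = 1/3 and c = 0.35 * (6/pi)^(1/3), d = 0.35 * L for spheres
  pop <- population_config(n_cells = 25, exponent_alpha = 1 / 3,
                           prefactor_c = 0.35 * (6 / pi)^(1 / 3),
                           diameter_noise_cv = 0, aspect_ratio_mean = 1,
                           aspect_ratio_sd = 0, seed = 11)
  tr <- population_truth(generate_population(pop))
  expect_equal(tr$d_true_um, 0.35 * tr$length_true_um, tolerance = 1e-12)
})

test_that("population generation is deterministic under the seed", {
  pop <- population_config(n_cells = 10, seed = 42)
  expect_identical(generate_population(pop), generate_population(pop))
  pop2 <- population_config(n_cells = 10, seed = 43)
  expect_false(identical(generate_population(pop),
                         generate_population(pop2)))
})

test_that("growing a population does not perturb earlier cells", {
  small <- generate_population(population_config(n_cells = 5, seed = 9))
  large <- generate_population(population_config(n_cells = 8, seed = 9))
  expect_identical(small, large[1:5])
})

test_that("sample volume median concentrates on the configured median", {
  # Monte-Carlo over 200 seeds, n = 500, median 60 fL
  hits <- vapply(1:200, function(s) {
    pop <- population_config(n_cells = 500, volume_median = 60,
                             volume_log10_sd = 0.25, seed = s)
    tr <- population_truth(generate_population(pop))
    abs(median(tr$volume_true_fL) - 60) < 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("spheroid semi-axes reproduce the ground-truth volume exactly", {
  cells <- generate_population(population_config(n_cells = 50, seed = 3))
  v_axes <- vapply(cells, function(c) {
    4 / 3 * pi * c$semi_major_um * c$semi_minor_um^2
  }, numeric(1))
  v_true <- vapply(cells, `[[`, numeric(1), "volume_true")
  expect_equal(v_axes, v_true, tolerance = 1e-9)
})

test_that("configuration errors are rejected", {
  expect_error(population_config(n_cells = 0), "n_cells")
  expect_error(population_config(volume_median = -5), "volume_median")
  expect_error(population_config(pixel_size = 0), "pixel_size")
  expect_error(render_config(cluster_peak_frame = 6, bud_emergence_frame = 6),
               "precede")
  expect_error(render_config(z_step = 0), "z_step")
})

test_that("rendered frames support recovery of the ground truth", {
  rc <- render_config(read_noise_sd = 0, psf_sigma = 1)
  cells <- generate_population(population_config(n_cells = 50, seed = 21))
  for (cell in cells) {
    fr <- render_cell_frame(cell, rc)
    m <- measure_ring(fr$image, threshold = 200, pixel_size = cell$pixel_size)
    expect_true(m$valid)
    # FWHM within 1 px of the true diameter at SNR >= 10
    expect_lt(abs(m$d_um - cell$ring_diameter_true), 1 * cell$pixel_size)
    # revolution volume of the rendered mask within 5% of the true volume
    v <- revolution_volume(fr$mask)
    expect_lt(abs(v / cell$volume_true - 1), 0.05)
  }
})

test_that("a frame without a ring yields no detection", {
  fr <- render_cell_frame(test_cell(), render_config(read_noise_sd = 0),
                          ring_present = FALSE)
  expect_null(detect_ring(fr$image, threshold = 200))
})

test_that("an explicitly undersized frame raises a render error", {
  expect_error(render_cell_frame(test_cell(d_ring = 5),
                                 render_config(), size = 20),
               "wider than")
})

test_that("z-stack reconstruction matches the analytic ellipsoid volume", {
  # semi-axes (3, 2, 2) um -> (4/3) pi * 3 * 4 = 50.27 fL
  cell <- test_cell(volume = 4 / 3 * pi * 3 * 2^2, aspect = 1.5,
                    orientation = 0)
  zs <- render_cell_zstack(cell, render_config(read_noise_sd = 0,
                                               z_step = 0.3))
  v <- reconstruct_volume_3d(zs$stack, zs$mask2d, zs$z_step)
  expect_lt(abs(v / 50.26548 - 1), 0.05)
})

test_that("z-stack gain changes do not move the reconstructed volume", {
  cell <- test_cell()
  zs <- render_cell_zstack(cell, render_config(read_noise_sd = 0))
  v1 <- reconstruct_volume_3d(zs$stack, zs$mask2d, zs$z_step)
  v2 <- reconstruct_volume_3d(zs$stack * 2, zs$mask2d, zs$z_step)
  expect_equal(v1, v2)
})

test_that("a zero-volume cell cannot be rendered as a z-stack", {
  cell <- test_cell()
  cell$volume_true <- 0
  expect_error(render_cell_zstack(cell, render_config()), "zero volume")
})

test_that("timecourse ring frames are exactly recoverable downstream", {
  cell <- test_cell()
  rc <- render_config(read_noise_sd = 0, frame_count_ring = 12)
  tc <- generate_timecourse(cell, rc, seed = 5)
  detected <- vapply(tc$frames, function(f) {
    measure_ring(f$ring, threshold = 200, pixel_size = 0.1)$valid
  }, logical(1))
  expect_identical(detected, tc$truth$ring_present)
  expect_identical(sum(detected), 12L)
})

test_that("timecourse ordering and determinism hold", {
  cell <- test_cell()
  rc <- render_config(read_noise_sd = 1.5)
  tc1 <- generate_timecourse(cell, rc, seed = 7)
  tc2 <- generate_timecourse(cell, rc, seed = 7)
  expect_identical(tc1, tc2)
  expect_lt(tc1$events$cluster_peak_frame, tc1$events$bud_emergence_frame)
  # the cluster envelope peaks at the stated frame
  expect_identical(which.max(tc1$truth$cluster_scale),
                   tc1$events$cluster_peak_frame)
})

test_that("aging tracks follow the configured diameter rule", {
  cell <- test_cell(volume = 50, d_ring = 1.1)
  # beta = 0: normalized diameters all 1
  flat <- normalize_aging(aging_records(
    generate_aging_track(cell, 15, beta = 0)))
  expect_equal(flat$d_norm, rep(1, 15))
  expect_equal(flat$V_norm[1], 1)
  expect_equal(flat$d_norm[1], 1)
  # beta = 0.15, noiseless: log-log fit recovers the exponent
  rec <- normalize_aging(aging_records(
    generate_aging_track(cell, 15, beta = 0.15)))
  fit <- fit_power_law(rec$d_norm, rec$V_norm)
  expect_lt(abs(fit$slope - 0.15), 0.005)
})
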