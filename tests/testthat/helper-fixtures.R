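# Rasterization helpers used across the measurement tests: shapes are drawn
# on pixel centers, matching the conventions of the package's own rasters.

disk_mask <- function(r, size = 2 * ceiling(r) + 5) {
  c0 <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  (x - c0)^2 + (y - c0)^2 <= r^2
}

ellipse_mask <- function(a, b, theta = 0, size = 2 * ceiling(a) + 5) {
  c0 <- (size + 1) / 2
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  u <- (x - c0) * cos(theta) + (y - c0) * sin(theta)
  v <- -(x - c0) * sin(theta) + (y - c0) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# An axis-aligned bright bar on a dark background.
bar_image <- function(len, thick, size = 60, value = 100, background = 0,
                      center = (size + 1) / 2) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  img <- matrix(background, size, size)
  img[abs(x - center) <= len / 2 & abs(y - center) <= thick / 2] <- value
  img
}

circle_contour <- function(r, n, center = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(phi), y = center[2] + r * sin(phi))
}

# A small default cell used by rendering tests.
test_cell <- function(volume = 100, aspect = 1.2, d_ring = 1.5,
                      d_cluster = 1.2, orientation = 0.3,
                      pixel_size = 0.1, id = "test") {
  ringscale:::make_synthetic_cell(volume, aspect, d_ring, d_cluster,
                                  orientation, pixel_size, id)
}
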