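# Low-level raster operations shared by the measurement modules.
#
# Images are numeric matrices indexed [row, col]; pixel centers sit at integer
# coordinates with x = column and y = row (1-based). All filters use
# replicate-padding at the borders, matching the behavior of the region-based
# tools the measurement conventions come from.

# Shift a matrix by (dy, dx) with replicated edges.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# k x k box (mean) filter, k odd, replicate borders.
mean_filter <- function(img, k = 3L) {
  stopifnot(k %% 2 == 1)
  r <- (k - 1L) / 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (dy in -r:r) for (dx in -r:r) out <- out + shift_mat(img, dy, dx)
  out / (k * k)
}

# k x k maximum filter, k odd, replicate borders.
max_filter <- function(img, k = 5L) {
  stopifnot(k %% 2 == 1)
  r <- (k - 1L) / 2L
  out <- img
  for (dy in -r:r) for (dx in -r:r) out <- pmax(out, shift_mat(img, dy, dx))
  out
}

# 2 x 2 averaging ("four-pixel average") filter used for background
# estimation; anchored at the top-left pixel of each 2 x 2 block.
avg4_filter <- function(img) {
  (img + shift_mat(img, 0L, -1L) + shift_mat(img, -1L, 0L) +
     shift_mat(img, -1L, -1L)) / 4
}

# Separable Gaussian blur (the point-spread-function model); kernel truncated
# at 4 sigma, replicate borders. sigma = 0 returns the input unchanged.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(w)) out <- out + w[i] * shift_mat(img, (-r:r)[i], 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(w)) out2 <- out2 + w[i] * shift_mat(out, 0L, (-r:r)[i])
  out2
}

# 8-connected component labeling by iterative minimum-label propagation.
# Components are relabeled 1..k in order of first occurrence in column-major
# scan order, which makes tie-breaking by "lowest label" deterministic.
label_components <- function(bw) {
  stopifnot(is.matrix(bw))
  lab <- matrix(0L, nrow(bw), ncol(bw))
  fg <- which(bw)
  if (length(fg) == 0L) return(lab)
  lab[fg] <- seq_along(fg)
  big <- length(fg) + 1L
  repeat {
    prev <- lab
    l <- lab
    l[l == 0L] <- big
    nb <- l
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nb <- pmin(nb, shift_mat(l, dy, dx))
    }
    upd <- pmin(l, nb)
    upd[lab == 0L] <- 0L
    lab <- upd
    if (identical(lab, prev)) break
  }
  # compact relabel in scan order
  u <- unique(lab[fg])
  lab[fg] <- match(lab[fg], u)
  lab
}

# Moment-equivalent ellipse of a set of foreground pixels, using the
# normalized second central moments of unit-square pixels (the +1/12 term)
# and the 4*sqrt(eigenvalue) axis-length convention of regionprops-style
# region analysis. `idx` is the arr.ind matrix (row, col) of the pixels.
region_moments <- function(idx) {
  y <- idx[, 1]; x <- idx[, 2]
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  uxx <- sum((x - cx)^2) / n + 1 / 12
  uyy <- sum((y - cy)^2) / n + 1 / 12
  uxy <- sum((x - cx) * (y - cy)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  # orientation of the major axis, in [-pi/2, pi/2)
  theta <- if (uxy == 0 && uxx >= uyy) 0 else atan2(2 * uxy, uxx - uyy) / 2
  if (theta >= pi / 2) theta <- theta - pi
  if (theta < -pi / 2) theta <- theta + pi
  list(centroid = c(x = cx, y = cy),
       major_px = 4 * sqrt(l1),
       minor_px = 4 * sqrt(max(l2, 0)),
       orientation = theta,
       area_px = n)
}

# Bilinear interpolation of image values at continuous (x, y) positions.
# Coordinates are clamped to the image domain.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}
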