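# Shared fixtures and independent brute-force oracles.

# Build a fluorescence image from channel matrices.
make_img <- function(r, g, b = NULL, ...) {
  r <- as.matrix(r); g <- as.matrix(g)
  if (is.null(b)) b <- matrix(0L, nrow(r), ncol(r))
  px <- array(0L, dim = c(nrow(r), ncol(r), 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- as.matrix(b)
  fluorescence_image(px, ...)
}

rand_img <- function(h, w) {
  make_img(matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w),
           matrix(sample(0:255, h * w, TRUE), h, w))
}

# Star-shaped simple polygon: jittered regular angles (every angular gap
# stays below pi, which guarantees simplicity) with random radii.
rand_star_polygon <- function(cx, cy, rmin, rmax, n_vertices = 8) {
  th <- 2 * pi * (seq_len(n_vertices) - 1 + runif(n_vertices, 0, 0.45)) /
    n_vertices
  rad <- runif(n_vertices, rmin, rmax)
  polygon_roi(cbind(cx + rad * cos(th), cy + rad * sin(th)), tooth_id = "T")
}

# Independent even-odd point-in-polygon test for a single point
# (textbook crossing-number formulation, scalar loop).
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- v[j, 1] + (py - v[j, 2]) * (v[i, 1] - v[j, 1]) /
        (v[i, 2] - v[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force per-pixel mask for a polygon.
oracle_polygon_mask <- function(v, h, w) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    m[i, j] <- oracle_point_in_polygon(j - 0.5, i - 0.5, v)
  m
}

# Brute-force scalar ratio rule.
oracle_ratio_px <- function(r, g) {
  if (g > 0) r %/% g else if (r > 0) 255L else 0L
}

# Brute-force coverage: double loop over pixels, no shared code with the
# implementation.
oracle_coverage <- function(img, roi, threshold = 1) {
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  n_roi <- 0L; n_plq <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (oracle_point_in_polygon(j - 0.5, i - 0.5, roi$vertices)) {
      n_roi <- n_roi + 1L
      val <- oracle_ratio_px(img$pixels[i, j, 1], img$pixels[i, j, 2])
      if (val >= threshold) n_plq <- n_plq + 1L
    }
  }
  list(roi_pixels = n_roi, plaque_pixels = n_plq,
       coverage_pct = 100 * n_plq / n_roi)
}
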