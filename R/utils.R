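# Shared angle and geometry helpers.
#
# Image coordinate convention used throughout the package: a frame is a
# numeric matrix with dim1 = x (rightward) and dim2 = y (downward), matching
# EBImage; pixel centres are at integer coordinates, 1-based. Angles are
# measured from the +x axis toward +y (clockwise on screen), in radians
# unless a function says degrees.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# wrap into [0, 2*pi)
wrap_2pi <- function(a) a %% (2 * pi)

# wrap into (-pi, pi]
wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# signed angle from vector u to vector v, in (-pi, pi]
signed_angle <- function(u, v) {
  atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])
}

# cumulative unwrap of an angle series (removes 2*pi jumps)
unwrap_angle <- function(a) {
  if (length(a) < 2) return(a)
  d <- wrap_pi(diff(a))
  a[1] + c(0, cumsum(d))
}

# Euclidean distance between rows of two 2-col matrices / vectors
pt_dist <- function(p, q) sqrt(sum((p - q)^2))

# cumulative chord arc length of an n x 2 polyline
arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

cum_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# resample an n x 2 polyline at m equally spaced arc-length positions
resample_polyline <- function(pts, m) {
  s <- cum_arc(pts)
  if (s[length(s)] == 0) return(pts[rep(1, m), , drop = FALSE])
  grid <- seq(0, s[length(s)], length.out = m)
  cbind(stats::approx(s, pts[, 1], xout = grid, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = grid, ties = "ordered")$y)
}

# binary erosion with a 3 x 3 square structuring element, applied n times
erode3x3 <- function(mask, times = 1L) {
  m <- mask > 0
  for (i in seq_len(times)) {
    nx <- nrow(m); ny <- ncol(m)
    p <- matrix(FALSE, nx + 2L, ny + 2L)
    p[2:(nx + 1L), 2:(ny + 1L)] <- m
    r <- p[1:nx, 1:ny] & p[2:(nx + 1L), 1:ny] & p[3:(nx + 2L), 1:ny] &
         p[1:nx, 2:(ny + 1L)] & p[2:(nx + 1L), 2:(ny + 1L)] & p[3:(nx + 2L), 2:(ny + 1L)] &
         p[1:nx, 3:(ny + 2L)] & p[2:(nx + 1L), 3:(ny + 2L)] & p[3:(nx + 2L), 3:(ny + 2L)]
    m <- r
  }
  storage.mode(m) <- "integer"
  m
}

# 4-connected component labelling (EBImage)
label_components <- function(mask) {
  EBImage::bwlabel(mask > 0)
}

# pixel coordinates (x, y) of component `id` in a label matrix
component_pixels <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx  # n x 2, (x, y)
}

# centroid of an n x 2 pixel set, optionally intensity-weighted
pixel_centroid <- function(pts, w = NULL) {
  if (is.null(w)) colMeans(pts)
  else colSums(pts * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
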