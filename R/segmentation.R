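#' Segment larva cores in one frame
#'
#' Computes the difference image (background minus frame, so larvae become
#' bright), binarizes it at the configured absolute threshold, applies a
#' 3x3 erosion twice, and returns the connected components of the eroded
#' mask whose area lies within the configured core-area bounds.
#'
#' @param frame,background Intensity matrices of identical shape (the
#'   background typically from [estimate_background()]).
#' @param cfg A [larva_config()].
#' @return A list with `binary` (pre-erosion 0/1 matrix), `eroded` (0/1
#'   matrix after double erosion), `labels` (labelled eroded mask) and
#'   `cores`: a list of candidate cores, each with `centroid` (x, y,
#'   intensity-weighted by the difference image), `area` (px^2), `pixels`
#'   (n x 2) and `label`.
#' @export
segment_cores <- function(frame, background, cfg = larva_config()) {
  stopifnot(all(dim(frame) == dim(background)))
  diffimg <- background - frame
  binary <- diffimg > cfg$binarize_threshold
  eroded <- erode3x3(binary, 2L)
  labels <- label_components(eroded)
  cores <- list()
  nmax <- max(labels)
  if (nmax > 0) {
    areas <- tabulate(labels[labels > 0], nbins = nmax)
    keep <- which(areas >= cfg$core_area_min_px2 & areas <= cfg$core_area_max_px2)
    for (id in keep) {
      pts <- component_pixels(labels, id)
      w <- diffimg[cbind(pts[, 1], pts[, 2])]
      cores[[length(cores) + 1L]] <- list(
        centroid = pixel_centroid(pts, w),
        area = nrow(pts), pixels = pts, label = id)
    }
  }
  storage.mode(binary) <- "integer"
  list(binary = binary, eroded = eroded, labels = labels,
       cores = cores, diff = diffimg)
}

#' Heading of a larva core from image moments
#'
#' The heading axis is the principal axis of the central second-order
#' moments of the core pixels. The axis is disambiguated to point
#' head-forward using the third-order moment (skewness) of the pixel
#' distribution projected on the axis: the head end is wider and denser,
#' so the projected distribution has its long thin tail pointing toward
#' the trunk, i.e. the skewness is negative in the head direction.
#'
#' @param pixels n x 2 matrix of core pixel coordinates, optionally with a
#'   weight vector `w` (e.g. difference-image intensities).
#' @param w Optional pixel weights.
#' @param prev_heading Previous frame's heading (rad), used when the
#'   component is too isotropic to orient.
#' @return Heading angle in `[0, 2*pi)` with attribute `degenerate`
#'   (logical).
#' @export
compute_heading <- function(pixels, w = NULL, prev_heading = NULL) {
  stopifnot(nrow(pixels) >= 3)
  if (is.null(w)) w <- rep(1, nrow(pixels))
  w <- w / sum(w)
  mx <- sum(pixels[, 1] * w); my <- sum(pixels[, 2] * w)
  dx <- pixels[, 1] - mx; dy <- pixels[, 2] - my
  mxx <- sum(dx^2 * w); myy <- sum(dy^2 * w); mxy <- sum(dx * dy * w)
  degen <- (mxx - myy)^2 + 4 * mxy^2 < 1e-9 * (mxx + myy)^2
  if (degen) {
    theta <- if (!is.null(prev_heading)) prev_heading else 0
    theta <- wrap_2pi(theta)
    attr(theta, "degenerate") <- TRUE
    return(theta)
  }
  axis <- 0.5 * atan2(2 * mxy, mxx - myy)
  v <- c(cos(axis), sin(axis))
  proj <- dx * v[1] + dy * v[2]
  m3 <- sum(proj^3 * w)
  # skewness points toward the thin (trunk) side; the head is the other way
  theta <- if (m3 > 0) wrap_2pi(axis + pi) else wrap_2pi(axis)
  if (abs(m3) < 1e-6 * (mxx + myy)^1.5 && !is.null(prev_heading)) {
    # near-symmetric component: keep the orientation consistent in time
    if (abs(wrap_pi(theta - prev_heading)) > pi / 2)
      theta <- wrap_2pi(theta + pi)
  }
  attr(theta, "degenerate") <- FALSE
  theta
}
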