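#' Detect circular wells in a frame
#'
#' Wells are bright filled disks on a darker surround (or the reverse with
#' `polarity = "dark"`). Detection thresholds the frame at the midpoint
#' between the two intensity modes, labels connected components, keeps
#' round components (area within 25% of a disk of the equivalent radius)
#' and returns their centres and radii. This replaces a voting circular
#' Hough transform, which reduces to the same centre/radius estimate for
#' filled, well-separated disks.
#'
#' @param frame A width x height intensity matrix (one video frame), or a
#'   `larva_video` (its first frame is used).
#' @param expected Expected number of wells.
#' @param polarity `"bright"` (default) if wells are brighter than the
#'   surround, `"dark"` otherwise.
#' @param min_radius_px Components with equivalent radius below this are
#'   ignored (noise, larvae).
#' @return A data.frame of well ROIs (`index`, `cx`, `cy`, `r`), sorted
#'   row-major by centre.
#' @export
detect_wells <- function(frame, expected, polarity = c("bright", "dark"),
                         min_radius_px = 20) {
  polarity <- match.arg(polarity)
  if (inherits(frame, "larva_video")) frame <- frame$frames[[1]]
  stopifnot(is.matrix(frame), expected >= 1)
  thr <- (min(frame) + max(frame)) / 2
  mask <- if (polarity == "bright") frame > thr else frame < thr
  if (!any(mask))
    stop("well detection found 0 circles, expected ", expected, call. = FALSE)
  lab <- label_components(mask)
  nmax <- max(lab)
  found <- list()
  for (id in seq_len(nmax)) {
    pts <- component_pixels(lab, id)
    area <- nrow(pts)
    r_eq <- sqrt(area / pi)
    if (r_eq < min_radius_px) next
    ctr <- colMeans(pts)
    # roundness: a filled disk has all pixels within ~r_eq of the centre
    rad <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    if (stats::quantile(rad, 0.99) > 1.25 * r_eq) next
    found[[length(found) + 1L]] <- c(ctr[1], ctr[2], r_eq)
  }
  if (length(found) != expected)
    stop("well detection found ", length(found), " circle(s), expected ",
         expected, call. = FALSE)
  m <- do.call(rbind, found)
  # row-major sort: group into rows by cy, then sort by cx
  o <- order(round(m[, 2] / (2 * stats::median(m[, 3]))), m[, 1])
  data.frame(index = seq_len(expected), cx = m[o, 1], cy = m[o, 2],
             r = m[o, 3])
}

#' Estimate the static background of a well
#'
#' The background is the pixel-wise maximum over frames: larvae are darker
#' than the background, so any pixel a moving larva vacates at least once
#' recovers its true background value.
#'
#' @param frames List of intensity matrices, or a `larva_video`.
#' @param roi Optional well ROI (one row of [detect_wells()] output); if
#'   given, frames are cropped to the bounding box of the well first.
#' @return The background matrix (cropped to `roi` if given, with
#'   attributes `x_off`/`y_off` giving the crop offset).
#' @export
estimate_background <- function(frames, roi = NULL) {
  if (inherits(frames, "larva_video")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 1)
  crop <- make_crop(frames[[1]], roi)
  bg <- crop(frames[[1]])
  for (i in seq_along(frames)[-1]) bg <- pmax(bg, crop(frames[[i]]))
  bg
}

# returns a cropping closure for a well ROI; the cropped matrix carries
# x_off/y_off attributes so pixel coordinates can be mapped back
make_crop <- function(frame, roi) {
  if (is.null(roi)) return(identity)
  x0 <- max(1L, floor(roi$cx - roi$r)); x1 <- min(nrow(frame), ceiling(roi$cx + roi$r))
  y0 <- max(1L, floor(roi$cy - roi$r)); y1 <- min(ncol(frame), ceiling(roi$cy + roi$r))
  function(f) {
    g <- f[x0:x1, y0:y1, drop = FALSE]
    attr(g, "x_off") <- x0 - 1L; attr(g, "y_off") <- y0 - 1L
    g
  }
}
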