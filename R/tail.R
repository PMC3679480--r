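#' Extract the full-body component of a larva
#'
#' The full body is the 4-connected component of the pre-erosion binary
#' image that contains the larva's core centroid. If the centroid falls on
#' a background pixel (it is a weighted mean), the 3x3 neighbourhood is
#' searched.
#'
#' @param binary Pre-erosion 0/1 matrix from [segment_cores()], or a
#'   pre-labelled matrix (integer labels, attribute `labelled = TRUE`).
#' @param centroid Core centroid (x, y).
#' @return A `full_body` list: `pixels` (n x 2), `label`, `labels` (the
#'   labelled matrix, reusable for other larvae in the same frame), `area`.
#' @export
extract_full_body <- function(binary, centroid) {
  labels <- if (isTRUE(attr(binary, "labelled"))) binary
            else label_components(binary)
  attr(labels, "labelled") <- TRUE
  cx <- as.integer(round(centroid[1])); cy <- as.integer(round(centroid[2]))
  lab <- 0L
  for (dx in c(0L, -1L, 1L)) {
    for (dy in c(0L, -1L, 1L)) {
      x <- cx + dx; y <- cy + dy
      if (x >= 1 && y >= 1 && x <= nrow(labels) && y <= ncol(labels) &&
          labels[x, y] > 0) { lab <- labels[x, y]; break }
    }
    if (lab > 0) break
  }
  if (lab == 0)
    stop("body-missing: core centroid has no foreground pixel in its 3x3 neighbourhood",
         call. = FALSE)
  pts <- component_pixels(labels, lab)
  structure(list(pixels = pts, label = lab, labels = labels,
                 area = nrow(pts)), class = "full_body")
}

# outer contour of a full-body component, in border-following order,
# 1-based (x, y) coordinates
body_contour <- function(body) {
  mask <- body$labels == body$label
  storage.mode(mask) <- "integer"
  oc <- EBImage::ocontour(mask)
  ct <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1
  ct
}

#' Locate the tail tip on the body contour
#'
#' Implements the candidate-point procedure: the body contour (traced by
#' border following) is expressed in a frame rotated so the heading axis is
#' parallel to the y-axis with the head at the top. Reference point A1 is
#' the contour point nearest the head centre and A2 its mirror across the
#' head axis. The contour points of minimal/maximal x and y caudal to
#' A1/A2 are tail-tip candidates; the maximal-y (most caudal) candidate
#' must additionally satisfy the soft asymmetry bound. For each candidate
#' the contour-arc distances d1, d2 to A1 and A2 are measured in contour
#' steps; candidates with |d1 - d2| / (d1 + d2) above the hard bound are
#' excluded. Among survivors the tip is the candidate with the sharpest
#' contour turn (largest scalar product of the two unit vectors pointing
#' away from the candidate along the contour).
#'
#' @param body A `full_body` from [extract_full_body()].
#' @param core Core centroid (x, y) = head centre.
#' @param heading Heading angle (rad).
#' @param cfg A [larva_config()].
#' @return The tip point (x, y) in image coordinates, with attributes
#'   `contour`, `tip_idx`, `iA1`, `iA2` for downstream midline extraction;
#'   or `NULL` if no candidate survives.
#' @export
find_tail_tip <- function(body, core, heading, cfg = larva_config()) {
  ct <- body_contour(body)
  n <- nrow(ct)
  if (n < 8) return(NULL)
  # rotate so the heading maps to -y (head at top, tail toward +y)
  del <- -pi / 2 - heading
  Rm <- matrix(c(cos(del), sin(del), -sin(del), cos(del)), 2, 2)
  rot <- sweep(ct, 2, core) %*% t(Rm)
  iA1 <- which.min((ct[, 1] - core[1])^2 + (ct[, 2] - core[2])^2)
  # A2: contour point nearest the reflection of A1 across the head axis
  # (in the rotated frame the head axis is the y-axis: mirror x)
  refl <- c(-rot[iA1, 1], rot[iA1, 2])
  iA2 <- which.min((rot[, 1] - refl[1])^2 + (rot[, 2] - refl[2])^2)
  y_head <- max(rot[iA1, 2], rot[iA2, 2])
  caudal <- rot[, 2] > y_head
  if (!any(caudal)) return(NULL)
  cand_idx <- c(
    which(caudal)[which.min(rot[caudal, 1])],
    which(caudal)[which.max(rot[caudal, 1])],
    which(caudal)[which.min(rot[caudal, 2])],
    maxy = which(caudal)[which.max(rot[caudal, 2])])
  is_maxy <- seq_along(cand_idx) == 4L
  keep <- logical(length(cand_idx))
  ratio <- numeric(length(cand_idx))
  for (k in seq_along(cand_idx)) {
    d <- contour_arc_dists(n, cand_idx[k], iA1, iA2)
    ratio[k] <- if (d[1] + d[2] > 0) abs(d[1] - d[2]) / (d[1] + d[2]) else 1
    keep[k] <- ratio[k] <= cfg$candidate_ratio_hard &&
      (!is_maxy[k] || ratio[k] <= cfg$candidate_ratio_soft)
  }
  cand_idx <- unique(cand_idx[keep])
  if (!length(cand_idx)) return(NULL)
  k_step <- max(3L, n %/% 30L)
  score <- vapply(cand_idx, function(i) {
    u1 <- ct[(i - 1 + k_step) %% n + 1, ] - ct[i, ]
    u2 <- ct[(i - 1 - k_step) %% n + 1, ] - ct[i, ]
    n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
    if (n1 == 0 || n2 == 0) return(-Inf)
    sum(u1 * u2) / (n1 * n2)
  }, 0)
  tip_idx <- cand_idx[which.max(score)]
  tip <- ct[tip_idx, ]
  attr(tip, "contour") <- ct
  attr(tip, "tip_idx") <- tip_idx
  attr(tip, "iA1") <- iA1
  attr(tip, "iA2") <- iA2
  tip
}

# arc distances (in contour steps) from index i to iA1 avoiding iA2, and
# to iA2 avoiding iA1, on a closed contour of n points
contour_arc_dists <- function(n, i, iA1, iA2) {
  fwd <- function(a, b) (b - a) %% n
  d1 <- if (fwd(i, iA2) < fwd(i, iA1)) fwd(iA1, i) else fwd(i, iA1)
  d2 <- if (fwd(i, iA1) < fwd(i, iA2)) fwd(iA2, i) else fwd(i, iA2)
  c(d1, d2)
}

# index sequence along the closed contour from `from` to `to` not passing
# through `avoid`
arc_indices <- function(n, from, to, avoid) {
  fwd <- (to - from) %% n
  via <- (avoid - from) %% n
  if (via < fwd) {
    # go backward
    len <- (from - to) %% n
    (from - seq(0, len)) %% n + ifelse((from - seq(0, len)) %% n == 0, n, 0)
  } else {
    (from + seq(0, fwd) - 1) %% n + 1
  }
}

#' Compute the 10-point tail midline
#'
#' The left and right contour arcs running from the two head reference
#' points to the tail tip are resampled to equal point counts; the raw
#' midline is their pointwise mean, smoothed with a spline and resampled
#' to 10 equally arc-spaced points from the head centre to the tip.
#'
#' @param tip Tip object from [find_tail_tip()] (carries the contour and
#'   split indices).
#' @param head_origin Midline origin: the head/trunk boundary point
#'   (core centroid shifted tailward by one head radius).
#' @param cfg A [larva_config()].
#' @return A `tail_midline` list: `points` (10 x 2, head first),
#'   `length_mm`, `valid` (length within the configured bounds).
#' @export
compute_midline <- function(tip, head_origin, cfg = larva_config()) {
  ct <- attr(tip, "contour")
  n <- nrow(ct)
  i1 <- arc_indices(n, attr(tip, "iA1"), attr(tip, "tip_idx"), attr(tip, "iA2"))
  i2 <- arc_indices(n, attr(tip, "iA2"), attr(tip, "tip_idx"), attr(tip, "iA1"))
  if (length(i1) < 3 || length(i2) < 3) {
    return(structure(list(points = NULL, length_mm = NA_real_, valid = FALSE),
                     class = "tail_midline"))
  }
  m <- 40L
  a1 <- resample_polyline(ct[i1, , drop = FALSE], m)
  a2 <- resample_polyline(ct[i2, , drop = FALSE], m)
  mid <- (a1 + a2) / 2
  # smoothing spline over arc length, then resample to 10 points
  s <- cum_arc(mid)
  if (s[length(s)] > 0 && length(unique(s)) >= 8) {
    df <- min(cfg$midline_spline_df, length(unique(s)) - 2)
    fx <- stats::smooth.spline(s, mid[, 1], df = df)
    fy <- stats::smooth.spline(s, mid[, 2], df = df)
    mid <- cbind(stats::predict(fx, s)$y, stats::predict(fy, s)$y)
  }
  # the raw midline starts near the core centre, rostral of the
  # head/trunk boundary; drop that stretch so prepending the head origin
  # does not double the path back on itself
  k <- min(8L, nrow(mid))
  u_tail <- mid[k, ] - mid[1, ]
  nu <- sqrt(sum(u_tail^2))
  if (nu > 0) {
    u_tail <- u_tail / nu
    proj <- (mid[, 1] - head_origin[1]) * u_tail[1] +
            (mid[, 2] - head_origin[2]) * u_tail[2]
    keep <- proj > 0
    if (sum(keep) >= 3) mid <- mid[keep, , drop = FALSE]
  }
  full <- rbind(head_origin, mid)
  pts <- resample_polyline(full, 10L)
  len_mm <- arc_length(pts) * cfg$pixel_size_mm
  structure(list(points = pts, length_mm = len_mm,
                 valid = len_mm >= cfg$tail_length_min_mm &&
                         len_mm <= cfg$tail_length_max_mm),
            class = "tail_midline")
}

#' Signed tail-bending angle
#'
#' The angle between the tailward body axis (heading reversed) and the
#' line from the head centre to the tail tip, in degrees, in (-180, 180].
#' The sign is positive when the tip lies counterclockwise from the
#' tailward axis in image coordinates (x right, y down), i.e. toward the
#' larva's left as seen by the camera; mirroring the image negates it.
#'
#' @param midline A `tail_midline` (its first and last points are the head
#'   centre and the tip), or a 2-column matrix.
#' @param heading Heading angle (rad).
#' @return Signed angle in degrees, or `NA` if the tip coincides with the
#'   head centre.
#' @export
compute_bend_angle <- function(midline, heading) {
  pts <- if (inherits(midline, "tail_midline")) midline$points else midline
  if (is.null(pts)) return(NA_real_)
  v <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v^2) == 0) return(NA_real_)
  rad2deg(signed_angle(c(-cos(heading), -sin(heading)), v))
}

#' Clean a raw bend-angle trace
#'
#' Invalid frames carry the previous valid value (leading invalid frames
#' take the first valid value); a temporal median filter then removes
#' single-frame glitches.
#'
#' @param angle_deg Raw per-frame bend angles (may contain `NA`).
#' @param valid Logical per-frame validity (defaults to `!is.na`).
#' @param cfg A [larva_config()] (median filter window).
#' @return Numeric vector of the same length, filled and median-filtered.
#' @export
clean_trace <- function(angle_deg, valid = NULL, cfg = larva_config()) {
  n <- length(angle_deg)
  if (n == 0) return(angle_deg)
  valid <- valid %||% !is.na(angle_deg)
  valid <- valid & !is.na(angle_deg)
  out <- angle_deg
  if (!any(valid)) return(rep(0, n))
  first <- which(valid)[1]
  if (first > 1) out[seq_len(first - 1)] <- out[first]
  for (i in seq_len(n)[-1]) if (!valid[i] && i > first) out[i] <- out[i - 1]
  w <- min(cfg$median_filter_frames, if (n %% 2 == 1) n else n - 1)
  if (w >= 3) out <- as.numeric(stats::runmed(out, w, endrule = "keep"))
  out
}
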