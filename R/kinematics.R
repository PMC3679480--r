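#' Global kinematic parameters of one movement
#'
#' Computes the per-bout summary parameters: number of oscillations
#' (sign-alternating bend-angle extrema exceeding the configured amplitude
#' threshold, two extrema per full left-right cycle), mean tail-beat
#' frequency (oscillations / duration), duration, heading direction range
#' (range of the unwrapped heading re-zeroed at bout onset), distance
#' traveled (path length of the core) and average speed
#' (distance / duration).
#'
#' @param event One event row (`start_frame`, `end_frame`) from
#'   [detect_movements()].
#' @param trace Cleaned full-trace bend angles (deg).
#' @param track n x 2 matrix of per-frame core positions (px).
#' @param heading Per-frame heading (rad), or `NULL` (heading range `NA`).
#' @param cfg A [larva_config()].
#' @return A one-row data.frame: `n_oscillations`, `tbf_hz`,
#'   `duration_ms`, `heading_range_deg`, `distance_mm`, `speed_mm_s`.
#' @export
compute_global_params <- function(event, trace, track, heading = NULL,
                                  cfg = larva_config()) {
  idx <- event$start_frame:event$end_frame
  if (length(idx) < 2) stop("degenerate event (fewer than 2 frames)",
                            call. = FALSE)
  a <- trace[idx]
  duration_s <- length(idx) / cfg$frame_rate_hz
  osc <- count_oscillations(a, cfg$oscillation_min_deg)
  tbf <- osc / duration_s
  hr <- NA_real_
  if (!is.null(heading)) {
    h <- unwrap_angle(heading[idx])
    h <- h - h[1]
    hr <- rad2deg(diff(range(h)))
  }
  steps <- sqrt(rowSums(diff(track[idx, , drop = FALSE])^2))
  dist_mm <- sum(steps) * cfg$pixel_size_mm
  data.frame(n_oscillations = osc, tbf_hz = tbf,
             duration_ms = duration_s * 1000,
             heading_range_deg = hr, distance_mm = dist_mm,
             speed_mm_s = dist_mm / duration_s)
}

# oscillations = alternating extrema with |angle| above `min_deg`, / 2
count_oscillations <- function(a, min_deg = 5) {
  ext <- local_extrema(a)
  ext <- ext[abs(a[ext]) > min_deg]
  if (!length(ext)) return(0)
  # keep only sign-alternating extrema (left-right alternation)
  s <- sign(a[ext])
  keep <- c(TRUE, s[-1] != s[-length(s)])
  sum(keep) / 2
}

# indices of local extrema, robust to flat-topped plateaus (e.g. after a
# median filter): sign changes of the slope with zeros carried forward;
# a plateau extremum reports its first index
local_extrema <- function(a) {
  n <- length(a)
  if (n < 3) return(integer(0))
  d <- sign(diff(a))
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  s <- d[nz]
  flips <- which(s[-1] != s[-length(s)])
  nz[flips] + 1L
}

#' Curvature kymograph of the tail over a movement
#'
#' For each frame the midline is fitted with a cubic spline in arc-length
#' parameterization and the unsigned curvature
#' c = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2) (derivatives with respect to
#' the distance along the tail) is evaluated on a fixed grid of arc
#' positions, then converted to 1/mm.
#'
#' @param midlines List of m x 2 midline matrices (head to tip), or a
#'   `10 x 2 x n_frames` array slice from `larva_tracks$midline`.
#' @param cfg A [larva_config()].
#' @param n_positions Number of arc-position samples (default 25).
#' @return A `curvature_kymograph` list: `curvature` (n_frames x
#'   n_positions matrix, 1/mm), `positions` (normalized arc positions,
#'   0 = head, 1 = tip), `valid` (per-frame flag; degenerate midlines give
#'   a zero row).
#' @export
compute_curvature <- function(midlines, cfg = larva_config(),
                              n_positions = 25) {
  if (is.array(midlines) && length(dim(midlines)) == 3)
    midlines <- lapply(seq_len(dim(midlines)[3]),
                       function(i) midlines[, , i])
  nf <- length(midlines)
  out <- matrix(0, nf, n_positions)
  ok <- logical(nf)
  pos <- seq(0, 1, length.out = n_positions)
  for (i in seq_len(nf)) {
    pts <- midlines[[i]]
    if (is.null(pts) || nrow(pts) < 5 || anyNA(pts)) next
    s <- cum_arc(pts)
    L <- s[length(s)]
    if (L <= 0 || any(diff(s) <= 0)) next
    fx <- stats::splinefun(s, pts[, 1], method = "fmm")
    fy <- stats::splinefun(s, pts[, 2], method = "fmm")
    g <- pos * L
    x1 <- fx(g, deriv = 1); y1 <- fy(g, deriv = 1)
    x2 <- fx(g, deriv = 2); y2 <- fy(g, deriv = 2)
    c_px <- abs(x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
    out[i, ] <- c_px / cfg$pixel_size_mm
    ok[i] <- TRUE
  }
  structure(list(curvature = out, positions = pos, valid = ok),
            class = "curvature_kymograph")
}
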