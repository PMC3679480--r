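#' Detect swim bouts in a bend-angle trace
#'
#' A frame is active when the bend angle deviates from the mean over the
#' ten surrounding frames (five before, five after, excluding the frame
#' itself; truncated at the trace boundaries) by more than the configured
#' threshold. Maximal runs of active frames form candidate events; events
#' separated by less than the merge gap are merged (a compound maneuver
#' with no bend-angle stabilization in between never separates in the
#' first place, since the trace stays active). Candidates are then
#' rejected unless (i) the straight-line core displacement between start
#' and end exceeds the minimum displacement, (ii) the in-event bend-angle
#' range exceeds the minimum range, and (iii) the eroded-mask pixel-change
#' count exceeds its minimum in at least one in-event frame pair. Criteria
#' (i) and (iii) are skipped when the corresponding input is `NULL` (e.g.
#' for traces without video).
#'
#' @param trace Cleaned bend-angle vector (deg), e.g. from
#'   [clean_trace()] or a column of [bend_traces()].
#' @param track Optional n x 2 matrix of per-frame core positions (px).
#' @param eroded_change Optional per-frame eroded-mask pixel-change counts
#'   (first entry may be `NA`).
#' @param cfg A [larva_config()].
#' @return A data.frame of events: `start_frame`, `end_frame` (1-based,
#'   inclusive), `start_s`, `end_s`, `n_frames`.
#' @export
detect_movements <- function(trace, track = NULL, eroded_change = NULL,
                             cfg = larva_config()) {
  n <- length(trace)
  if (!is.null(track) && nrow(track) != n)
    stop("trace and track lengths differ (", n, " vs ", nrow(track), ")",
         call. = FALSE)
  if (!is.null(eroded_change) && length(eroded_change) != n)
    stop("trace and eroded_change lengths differ", call. = FALSE)
  if (n == 0) return(empty_events(cfg))

  half <- cfg$move_window_frames / 2
  lo <- pmax(1, seq_len(n) - ceiling(half))
  hi <- pmin(n, seq_len(n) + floor(half))
  cs <- c(0, cumsum(trace))
  win_mean <- (cs[hi + 1] - cs[lo]) - trace
  win_mean <- win_mean / (hi - lo + 1 - 1)
  active <- abs(trace - win_mean) > cfg$move_angle_delta_deg

  ev <- runs_to_events(active)
  if (!nrow(ev)) return(empty_events(cfg))
  ev <- merge_events(ev, cfg$merge_gap_frames)

  keep <- rep(TRUE, nrow(ev))
  for (k in seq_len(nrow(ev))) {
    idx <- ev$start_frame[k]:ev$end_frame[k]
    if (diff(range(trace[idx])) <= cfg$min_angle_range_deg) keep[k] <- FALSE
    if (keep[k] && !is.null(track)) {
      disp <- pt_dist(track[ev$start_frame[k], ], track[ev$end_frame[k], ])
      if (disp <= cfg$min_displacement_px) keep[k] <- FALSE
    }
    if (keep[k] && !is.null(eroded_change)) {
      ch <- eroded_change[idx]
      if (!any(ch >= cfg$min_eroded_change_px, na.rm = TRUE)) keep[k] <- FALSE
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev$start_s <- (ev$start_frame - 1) / cfg$frame_rate_hz
  ev$end_s <- (ev$end_frame - 1) / cfg$frame_rate_hz
  ev$n_frames <- ev$end_frame - ev$start_frame + 1L
  ev
}

empty_events <- function(cfg) {
  data.frame(start_frame = integer(0), end_frame = integer(0),
             start_s = numeric(0), end_s = numeric(0), n_frames = integer(0))
}

runs_to_events <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)
  data.frame(start_frame = starts[k], end_frame = ends[k])
}

#' Merge events separated by less than a gap
#'
#' @param events Data.frame with `start_frame`, `end_frame`, time-ordered.
#' @param gap_frames Events whose between-gap (in frames) is smaller than
#'   this are merged. Idempotent: merging twice equals merging once.
#' @return Merged data.frame.
#' @export
merge_events <- function(events, gap_frames) {
  if (nrow(events) < 2) return(events)
  out <- events[1, , drop = FALSE]
  for (k in 2:nrow(events)) {
    gap <- events$start_frame[k] - out$end_frame[nrow(out)] - 1L
    if (gap < gap_frames) {
      out$end_frame[nrow(out)] <- max(out$end_frame[nrow(out)],
                                      events$end_frame[k])
    } else {
      out <- rbind(out, events[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
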