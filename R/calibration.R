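#' Calibration and threshold configuration
#'
#' Every numeric threshold of the pipeline is stored once, in physical units
#' (mm, mm^2, ms, degrees), together with the camera calibration needed to
#' convert them to pixels and frames at use sites. All downstream stages take
#' a `larva_config` object so that a single pixel size / frame rate change
#' propagates consistently.
#'
#' @param pixel_size_mm Length of one pixel side in mm (default 0.066, i.e.
#'   66 um per pixel).
#' @param frame_rate_hz Acquisition rate in frames per second (default 337).
#' @param core_area_min_mm2,core_area_max_mm2 Area bounds in mm^2 for a
#'   connected component of the twice-eroded binary image to count as a larva
#'   core (defaults 0.0871 and 0.8712, i.e. 20 and 200 px^2 at default
#'   calibration).
#' @param tail_length_min_mm,tail_length_max_mm Valid midline arc-length
#'   bounds in mm (defaults 1.32 and 3.96).
#' @param contact_area_mm2 Full-body component area above which two larvae
#'   are assumed to be touching (default 1.9).
#' @param contact_line_vs_threshold_mm Core-to-core distance below which the
#'   line-separation algorithm is used instead of intensity separation
#'   (default 1.32).
#' @param move_angle_delta_deg Deviation of the bend angle from its local
#'   running mean that marks a frame as active (default 1.15).
#' @param move_window_frames Number of surrounding frames for the running
#'   mean, split evenly before/after and excluding the current frame
#'   (default 10; 29.7 ms at 337 Hz).
#' @param merge_gap_ms Two events closer than this gap are merged
#'   (default 14.8, about 5 frames at 337 Hz).
#' @param min_displacement_mm Minimum straight-line core displacement of a
#'   genuine event (default 0.099).
#' @param min_angle_range_deg Minimum in-event bend-angle range of a genuine
#'   event (default 2.86).
#' @param candidate_ratio_soft,candidate_ratio_hard Contour-arc asymmetry
#'   ratio |d1 - d2| / (d1 + d2) bounds used during tail-tip selection: the
#'   soft bound (default 0.20) gates the most-caudal candidate, the hard
#'   bound (default 0.25) excludes any candidate.
#' @param binarize_threshold Absolute background-minus-frame difference (on a
#'   0-255 scale) above which a pixel is foreground (default 25).
#' @param min_eroded_change_px Minimum count of pixels differing between
#'   consecutive eroded masks for an event to count as true motion
#'   (default 3).
#' @param head_radius_mm Approximate head radius, used to place the midline
#'   origin at the head/trunk boundary (default 0.40).
#' @param median_filter_frames Window of the temporal median filter applied
#'   to the bend-angle trace (default 5, must be odd).
#' @param oscillation_min_deg Absolute bend-angle extremum threshold used
#'   when counting oscillations (default 5).
#' @param midline_spline_df Degrees of freedom of the smoothing spline
#'   fitted to the raw midline (default 6).
#'
#' @return An object of class `larva_config`: a validated named list with,
#'   in addition to the fields above, derived pixel/frame values
#'   (`core_area_min_px2`, `core_area_max_px2`, `tail_length_min_px`,
#'   `tail_length_max_px`, `contact_area_px2`, `contact_line_vs_threshold_px`,
#'   `min_displacement_px`, `merge_gap_frames`).
#' @examples
#' cfg <- larva_config()
#' cfg$tail_length_min_px  # 20 px at 66 um/px
#' @export
larva_config <- function(pixel_size_mm = 0.066,
                         frame_rate_hz = 337,
                         core_area_min_mm2 = 0.0871,
                         core_area_max_mm2 = 0.8712,
                         tail_length_min_mm = 1.32,
                         tail_length_max_mm = 3.96,
                         contact_area_mm2 = 1.9,
                         contact_line_vs_threshold_mm = 1.32,
                         move_angle_delta_deg = 1.15,
                         move_window_frames = 10,
                         merge_gap_ms = 14.8,
                         min_displacement_mm = 0.099,
                         min_angle_range_deg = 2.86,
                         candidate_ratio_soft = 0.20,
                         candidate_ratio_hard = 0.25,
                         binarize_threshold = 25,
                         min_eroded_change_px = 3,
                         head_radius_mm = 0.40,
                         median_filter_frames = 5,
                         oscillation_min_deg = 5,
                         midline_spline_df = 6) {
  cfg <- list(
    pixel_size_mm = pixel_size_mm,
    frame_rate_hz = frame_rate_hz,
    core_area_min_mm2 = core_area_min_mm2,
    core_area_max_mm2 = core_area_max_mm2,
    tail_length_min_mm = tail_length_min_mm,
    tail_length_max_mm = tail_length_max_mm,
    contact_area_mm2 = contact_area_mm2,
    contact_line_vs_threshold_mm = contact_line_vs_threshold_mm,
    move_angle_delta_deg = move_angle_delta_deg,
    move_window_frames = move_window_frames,
    merge_gap_ms = merge_gap_ms,
    min_displacement_mm = min_displacement_mm,
    min_angle_range_deg = min_angle_range_deg,
    candidate_ratio_soft = candidate_ratio_soft,
    candidate_ratio_hard = candidate_ratio_hard,
    binarize_threshold = binarize_threshold,
    min_eroded_change_px = min_eroded_change_px,
    head_radius_mm = head_radius_mm,
    median_filter_frames = median_filter_frames,
    oscillation_min_deg = oscillation_min_deg,
    midline_spline_df = midline_spline_df
  )
  validate_config(cfg)
  structure(add_derived(cfg), class = "larva_config")
}

# derived pixel/frame values are pure functions of the physical values
add_derived <- function(cfg) {
  px <- cfg$pixel_size_mm
  cfg$core_area_min_px2 <- cfg$core_area_min_mm2 / px^2
  cfg$core_area_max_px2 <- cfg$core_area_max_mm2 / px^2
  cfg$tail_length_min_px <- cfg$tail_length_min_mm / px
  cfg$tail_length_max_px <- cfg$tail_length_max_mm / px
  cfg$contact_area_px2 <- cfg$contact_area_mm2 / px^2
  cfg$contact_line_vs_threshold_px <- cfg$contact_line_vs_threshold_mm / px
  cfg$min_displacement_px <- cfg$min_displacement_mm / px
  cfg$head_radius_px <- cfg$head_radius_mm / px
  cfg$merge_gap_frames <- cfg$merge_gap_ms * cfg$frame_rate_hz / 1000
  cfg
}

validate_config <- function(cfg) {
  pos <- c("pixel_size_mm", "frame_rate_hz", "core_area_min_mm2",
           "core_area_max_mm2", "tail_length_min_mm", "tail_length_max_mm",
           "contact_area_mm2", "contact_line_vs_threshold_mm",
           "move_angle_delta_deg", "move_window_frames", "merge_gap_ms",
           "min_displacement_mm", "min_angle_range_deg",
           "candidate_ratio_soft", "candidate_ratio_hard",
           "binarize_threshold", "head_radius_mm", "median_filter_frames",
           "oscillation_min_deg", "midline_spline_df")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (!is.numeric(cfg$min_eroded_change_px) || cfg$min_eroded_change_px < 0)
    stop("config field 'min_eroded_change_px' must be non-negative",
         call. = FALSE)
  pairs <- list(c("core_area_min_mm2", "core_area_max_mm2"),
                c("tail_length_min_mm", "tail_length_max_mm"),
                c("candidate_ratio_soft", "candidate_ratio_hard"))
  for (p in pairs) {
    if (cfg[[p[1]]] >= cfg[[p[2]]])
      stop("config requires ", p[1], " < ", p[2], " (got ",
           cfg[[p[1]]], " >= ", cfg[[p[2]]], ")", call. = FALSE)
  }
  if (cfg$median_filter_frames %% 2 != 1)
    stop("config field 'median_filter_frames' must be odd", call. = FALSE)
  invisible(cfg)
}

#' Load a calibration configuration from a YAML file
#'
#' Reads a flat `key: value` document whose keys are the arguments of
#' [larva_config()]; unset keys keep their defaults. Unknown keys are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to the YAML config file, or `NULL` for all defaults.
#' @return A validated `larva_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(larva_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.null(vals)) vals <- list()
  known <- names(formals(larva_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(larva_config, vals)
}

#' Convert between physical and pixel/frame units
#'
#' @param cfg A `larva_config` object.
#' @param value_mm Length in mm.
#' @return `to_pixels()`: the length in pixels (exact floating division by
#'   the pixel size). `to_mm()` is its inverse. `to_frames()` converts a
#'   duration in ms to frames; `to_ms()` the reverse.
#' @examples
#' to_pixels(larva_config(), 1.32)  # 20
#' @export
to_pixels <- function(cfg, value_mm) value_mm / cfg$pixel_size_mm

#' @rdname to_pixels
#' @param value_px Length in pixels.
#' @export
to_mm <- function(cfg, value_px) value_px * cfg$pixel_size_mm

#' @rdname to_pixels
#' @param value_ms Duration in ms.
#' @export
to_frames <- function(cfg, value_ms) value_ms * cfg$frame_rate_hz / 1000

#' @rdname to_pixels
#' @param value_frames Duration in frames.
#' @export
to_ms <- function(cfg, value_frames) value_frames * 1000 / cfg$frame_rate_hz

#' @export
print.larva_config <- function(x, ...) {
  cat("<larva_config>\n")
  cat(sprintf("  pixel size: %g mm/px   frame rate: %g Hz\n",
              x$pixel_size_mm, x$frame_rate_hz))
  cat(sprintf("  core area: [%g, %g] mm^2  ([%g, %g] px^2)\n",
              x$core_area_min_mm2, x$core_area_max_mm2,
              x$core_area_min_px2, x$core_area_max_px2))
  cat(sprintf("  tail length: [%g, %g] mm  ([%g, %g] px)\n",
              x$tail_length_min_mm, x$tail_length_max_mm,
              x$tail_length_min_px, x$tail_length_max_px))
  cat(sprintf("  movement: delta %g deg over %d frames, merge %g ms, min %g mm / %g deg\n",
              x$move_angle_delta_deg, x$move_window_frames, x$merge_gap_ms,
              x$min_displacement_mm, x$min_angle_range_deg))
  invisible(x)
}
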