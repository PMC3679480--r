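# Reading and writing frame stacks, ground truth and stage tables.
#
# Frame stacks are exchanged as numbered 8-bit grayscale PNG sequences
# (frame_000001.png, ...); ground truth and run manifests as JSON; all
# tabular stage outputs as CSV with a header row.

#' Write / read a frame stack as a numbered PNG sequence
#'
#' @param video A `larva_video` or a list of intensity matrices (0-255,
#'   dim1 = x).
#' @param dir Output directory (created if needed).
#' @return `write_frames_png()` returns the file paths invisibly;
#'   `read_frames_png()` returns a list of integer matrices.
#' @export
write_frames_png <- function(video, dir) {
  frames <- if (inherits(video, "larva_video")) video$frames else video
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames)) {
    # png arrays are [row = y, col = x]
    png::writePNG(t(frames[[i]]) / 255, paths[i])
  }
  invisible(paths)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(paths)) stop("no frame_*.png files in ", dir, call. = FALSE)
  lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- t(a) * 255
    matrix(as.integer(round(m)), nrow(m), ncol(m))
  })
}

#' Write / read ground truth as JSON
#'
#' @param truth The `truth` element of a `larva_video`.
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$events <- as.data.frame(tr$events)
  tr
}

#' Flatten tracking results to per-frame tables
#'
#' @param tracks A `larva_tracks` (or list of them, one per well).
#' @param well_index Well number used in the output tables.
#' @return `track_table()`: data.frame `frame`, `well`, `larva`, `x`,
#'   `y`, `heading_rad`, `valid`. `tail_table()`: data.frame `frame`,
#'   `well`, `larva`, `x1`..`y10` (midline points), `tail_length_mm`,
#'   `bend_deg`, `valid`.
#' @export
track_table <- function(tracks, well_index = 1) {
  if (!inherits(tracks, "larva_tracks"))
    return(do.call(rbind, lapply(seq_along(tracks), function(k)
      track_table(tracks[[k]], k))))
  n <- tracks$n_frames
  do.call(rbind, lapply(seq_len(tracks$n_larvae), function(j) {
    data.frame(frame = seq_len(n), well = well_index, larva = j,
               x = tracks$core[, 1, j], y = tracks$core[, 2, j],
               heading_rad = tracks$heading[, j], valid = tracks$valid[, j],
               eroded_change = tracks$eroded_change[, j])
  }))
}

#' @rdname track_table
#' @export
tail_table <- function(tracks, well_index = 1) {
  if (!inherits(tracks, "larva_tracks"))
    return(do.call(rbind, lapply(seq_along(tracks), function(k)
      tail_table(tracks[[k]], k))))
  n <- tracks$n_frames
  cfg <- tracks$cfg
  do.call(rbind, lapply(seq_len(tracks$n_larvae), function(j) {
    pts <- tracks$midline[, , , j]          # 10 x 2 x frames
    d <- data.frame(frame = seq_len(n), well = well_index, larva = j)
    for (p in 1:10) {
      d[[paste0("x", p)]] <- pts[p, 1, ]
      d[[paste0("y", p)]] <- pts[p, 2, ]
    }
    len <- vapply(seq_len(n), function(i) {
      m <- pts[, , i]
      if (anyNA(m)) NA_real_ else arc_length(m) * cfg$pixel_size_mm
    }, 0)
    d$tail_length_mm <- len
    d$bend_deg <- tracks$bend_deg[, j]
    d$valid <- tracks$tail_valid[, j]
    d
  }))
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_stage_csv <- function(path, stage = NULL) {
  if (!file.exists(path))
    stop("missing input file '", path, "'",
         if (!is.null(stage)) paste0("; run the '", stage, "' stage first"),
         call. = FALSE)
  utils::read.csv(path)
}
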