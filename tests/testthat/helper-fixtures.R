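# Shared fixtures, built in code and memoized for the test run.

.fx <- new.env(parent = emptyenv())

fx_cfg <- function() larva_config()

# clean (larva-free) background frame for a given layout
fx_background <- function(layout) {
  key <- paste0("bg_", layout$width, "x", layout$height, "_",
                nrow(layout$wells))
  if (is.null(.fx[[key]]))
    .fx[[key]] <- render_video(layout, list(), 1, fx_cfg(), seed = 1,
                               noise_sd = 0)$frames[[1]]
  .fx[[key]]
}

# short clip of one larva doing an S then a T maneuver
fx_single_larva <- function() {
  if (is.null(.fx$single)) {
    cfg <- fx_cfg()
    lay <- well_layout(1, radius_px = 120)
    sc <- larva_script(1, x = lay$wells$cx - 30, y = lay$wells$cy,
                       heading_deg = 0,
                       events = data.frame(start_ms = c(50, 300),
                                           class = c("S", "T"),
                                           turn_sign = c(1, -1)))
    vid <- render_video(lay, list(sc), n_frames = 200, cfg = cfg,
                        seed = 3, noise_sd = 2)
    .fx$single <- list(layout = lay, video = vid,
                       background = fx_background(lay))
  }
  .fx$single
}

# tracking result for the single-larva clip
fx_single_tracks <- function() {
  if (is.null(.fx$single_tracks)) {
    f <- fx_single_larva()
    .fx$single_tracks <- track_well(f$video, f$video$wells[1, ], fx_cfg(),
                                    background = f$background)
  }
  .fx$single_tracks
}

# one segmented frame of the single-larva clip (straightest frame: 1)
fx_single_frame <- function(frame = 1) {
  f <- fx_single_larva()
  crop <- larvatrack:::make_crop(f$video$frames[[1]], f$video$wells[1, ])
  seg <- segment_cores(crop(f$video$frames[[frame]]), crop(f$background),
                       fx_cfg())
  ci <- crop(f$video$frames[[1]])
  list(seg = seg, crop = crop, video = f$video,
       x_off = attr(ci, "x_off"), y_off = attr(ci, "y_off"))
}

# crossing scripts for two larvae: straight paths through the well centre,
# crossing at angle `ang_deg`, head paths `offset_px` apart
fx_cross_scripts <- function(layout, ang_deg, offset_px, n_frames) {
  cx <- layout$wells$cx; cy <- layout$wells$cy
  a <- ang_deg * pi / 180
  tt <- seq(-60, 60, length.out = n_frames)
  pA <- cbind(cx + tt, rep(cy, n_frames), rep(0, n_frames))
  pB <- cbind(cx + tt * cos(a) - offset_px * sin(a),
              cy + tt * sin(a) + offset_px * cos(a),
              rep(ang_deg, n_frames))
  list(larva_script(1, path = pA), larva_script(1, path = pB))
}

# ground-truth contact frames: any two body sample points of the two
# larvae closer than `thresh` px
fx_contact_frames <- function(vid, thresh = 6) {
  n <- length(vid$frames)
  which(vapply(seq_len(n), function(i) {
    A <- rbind(vid$truth$midline[, , i, 1], vid$truth$core[i, , 1])
    B <- rbind(vid$truth$midline[, , i, 2], vid$truth$core[i, , 2])
    d <- as.matrix(stats::dist(rbind(A, B)))
    min(d[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B))]) < thresh
  }, TRUE))
}

# map tracked larva ids to ground-truth larvae by frame-1 positions
fx_identity_map <- function(tracks, vid) {
  nl <- tracks$n_larvae
  vapply(seq_len(nl), function(j)
    which.min(colSums((vid$truth$core[1, , , drop = FALSE][1, , ] -
                         tracks$core[1, , j])^2)), 0L)
}
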