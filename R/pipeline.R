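#' Run the tracking-to-interactions pipeline
#'
#' Chains the analysis stages through CSV/JSON files in an output
#' directory, so each stage can be re-run or inspected independently:
#'
#' * `simulate`: render a synthetic multi-well video (frames as a PNG
#'   sequence, ground truth as JSON, plus the larva-free background).
#' * `track`: detect wells, track cores and tails; writes `track.csv`
#'   and `tail.csv`.
#' * `detect`: segment bend-angle traces into movements and compute
#'   global kinematic parameters; writes `movements.csv`.
#' * `classify`: fit the maneuver classifier on ground-truth labels
#'   (`fit = TRUE`, synthetic runs) or apply a saved model, appending a
#'   `class` column; writes `movements_classified.csv` and `model.json`.
#' * `interact`: transition-index analysis of the classified movement
#'   sequence; writes `transitions.csv` and `transitions_summary.json`.
#' * `all`: every stage in order.
#'
#' A `manifest.json` recording inputs, configuration, seeds and output
#' row counts is updated after each stage.
#'
#' @param command One of `"simulate"`, `"track"`, `"detect"`,
#'   `"classify"`, `"interact"`, `"all"`.
#' @param out_dir Output directory.
#' @param cfg A [larva_config()] (or path to a YAML config file).
#' @param seed Integer seed for the synthetic stages.
#' @param n_wells,n_larvae,n_frames Scene parameters for `simulate`.
#' @param model Optional path to a saved classifier for `classify`
#'   (otherwise a model is fitted on ground-truth labels, which requires
#'   `truth.json` from `simulate`).
#' @param verbose Log per-stage timing and counts to stderr.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(command = c("all", "simulate", "track", "detect",
                                     "classify", "interact"),
                         out_dir, cfg = larva_config(), seed = 1,
                         n_wells = 1, n_larvae = 3, n_frames = 800,
                         model = NULL, verbose = TRUE) {
  command <- match.arg(command)
  if (is.character(cfg)) cfg <- load_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all")
    c("simulate", "track", "detect", "classify", "interact") else command
  man <- read_manifest(out_dir)
  man$config <- cfg[!vapply(cfg, is.function, TRUE)]
  man$seed <- seed
  for (st in stages) {
    t0 <- Sys.time()
    n_out <- switch(st,
      simulate = stage_simulate(out_dir, cfg, seed, n_wells, n_larvae,
                                n_frames),
      track = stage_track(out_dir, cfg, n_wells),
      detect = stage_detect(out_dir, cfg),
      classify = stage_classify(out_dir, cfg, model, seed),
      interact = stage_interact(out_dir, cfg))
    man$stages[[st]] <- list(rows = n_out,
                             elapsed_s = as.numeric(Sys.time() - t0,
                                                    units = "secs"))
    if (verbose)
      message(sprintf("[%s] %d rows in %.1f s", st, n_out,
                      man$stages[[st]]$elapsed_s))
    write_manifest(man, out_dir)
  }
  invisible(man)
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE)
  else list(stages = list())
}

write_manifest <- function(man, out_dir) {
  p <- file.path(out_dir, "manifest.json")
  tmp <- paste0(p, ".tmp")
  jsonlite::write_json(man, tmp, digits = NA, auto_unbox = TRUE)
  file.rename(tmp, p)   # atomic replace
  invisible(p)
}

# default synthetic scene: larvae drifting on rings inside each well with
# scheduled maneuvers drawn from the wild-type class frequencies
stage_simulate <- function(out_dir, cfg, seed, n_wells, n_larvae,
                           n_frames) {
  lay <- well_layout(n_wells, radius_px = 110)
  fps <- cfg$frame_rate_hz
  dur_ms <- n_frames * 1000 / fps
  larvae <- with_seed(seed, {
    out <- list()
    for (w in seq_len(n_wells)) {
      wr <- lay$wells[w, ]
      for (l in seq_len(n_larvae)) {
        ph0 <- 2 * pi * l / n_larvae + stats::runif(1, 0, 0.5)
        drift <- 0.35 * n_frames / fps          # rad over the clip
        ph <- ph0 + seq(0, drift, length.out = n_frames)
        r_ring <- wr$r * 0.6
        path <- cbind(wr$cx + r_ring * cos(ph), wr$cy + r_ring * sin(ph),
                      (ph + pi / 2) * 180 / pi)
        n_ev <- max(1, stats::rpois(1, dur_ms / 2220))
        starts <- sort(stats::runif(n_ev, 50, max(60, dur_ms - 400)))
        starts <- starts[c(TRUE, diff(starts) > 400)]
        ev <- data.frame(start_ms = starts,
                         class = sample(c("S", "T", "E"), length(starts),
                                        TRUE, prob = c(0.35, 0.48, 0.16)))
        out[[length(out) + 1L]] <- larva_script(w, path = path, events = ev)
      }
    }
    out
  })
  vid <- render_video(lay, larvae, n_frames, cfg, seed = seed + 1)
  bg <- render_video(lay, list(), 1, cfg, seed = 1, noise_sd = 0)
  write_frames_png(vid, file.path(out_dir, "frames"))
  png::writePNG(t(bg$frames[[1]]) / 255, file.path(out_dir, "background.png"))
  write_truth_json(vid$truth, file.path(out_dir, "truth.json"))
  jsonlite::write_json(lay$wells, file.path(out_dir, "wells.json"),
                       digits = NA)
  length(vid$frames)
}

stage_track <- function(out_dir, cfg, n_wells) {
  fdir <- file.path(out_dir, "frames")
  if (!dir.exists(fdir))
    stop("missing '", fdir, "'; run the 'simulate' stage first (or place a ",
         "PNG frame sequence there)", call. = FALSE)
  frames <- read_frames_png(fdir)
  bgp <- file.path(out_dir, "background.png")
  bg <- NULL
  if (file.exists(bgp)) {
    a <- png::readPNG(bgp); if (length(dim(a)) == 3) a <- a[, , 1]
    bg <- matrix(as.integer(round(t(a) * 255)), ncol(a), nrow(a))
  }
  wells <- detect_wells(frames[[1]], n_wells)
  tracks <- track_video(frames, cfg, wells = wells, background = bg)
  write_stage_csv(track_table(tracks), file.path(out_dir, "track.csv"))
  tl <- tail_table(tracks)
  write_stage_csv(tl, file.path(out_dir, "tail.csv"))
  nrow(tl)
}

stage_detect <- function(out_dir, cfg) {
  tr <- read_stage_csv(file.path(out_dir, "track.csv"), "track")
  tl <- read_stage_csv(file.path(out_dir, "tail.csv"), "track")
  out <- NULL
  for (w in unique(tr$well)) for (l in unique(tr$larva[tr$well == w])) {
    a <- tr[tr$well == w & tr$larva == l, ]
    b <- tl[tl$well == w & tl$larva == l, ]
    trace <- clean_trace(b$bend_deg, b$valid | !is.na(b$bend_deg), cfg)
    track <- cbind(a$x, a$y)
    ev <- detect_movements(trace, track, a$eroded_change, cfg)
    if (!nrow(ev)) next
    gp <- do.call(rbind, lapply(seq_len(nrow(ev)), function(k)
      compute_global_params(ev[k, ], trace, track, a$heading_rad, cfg)))
    out <- rbind(out, cbind(well = w, larva = l, ev, gp))
  }
  out <- out %||% data.frame()
  write_stage_csv(out, file.path(out_dir, "movements.csv"))
  nrow(out)
}

# feature matrix for all movements in a run directory
run_features <- function(out_dir, cfg) {
  mv <- read_stage_csv(file.path(out_dir, "movements.csv"), "detect")
  tr <- read_stage_csv(file.path(out_dir, "track.csv"), "track")
  tl <- read_stage_csv(file.path(out_dir, "tail.csv"), "track")
  X <- matrix(NA_real_, nrow(mv), 53)
  dur <- rep(NA_real_, nrow(mv)); ok <- logical(nrow(mv))
  for (k in seq_len(nrow(mv))) {
    w <- mv$well[k]; l <- mv$larva[k]
    a <- tr[tr$well == w & tr$larva == l, ]
    b <- tl[tl$well == w & tl$larva == l, ]
    trace <- clean_trace(b$bend_deg, cfg = cfg)
    fv <- tryCatch(extract_features(mv[k, ], trace, cbind(a$x, a$y), cfg),
                   error = function(e) NULL)
    if (!is.null(fv)) { X[k, ] <- fv$raw; dur[k] <- fv$duration_ms; ok[k] <- TRUE }
  }
  list(mv = mv, X = X, dur = dur, ok = ok)
}

stage_classify <- function(out_dir, cfg, model, seed) {
  ft <- run_features(out_dir, cfg)
  mv <- ft$mv
  if (is.null(model)) {
    # no model given: train on the synthetic archetype bank
    ts <- synthetic_training_set(240, cfg, seed = seed)
    m <- fit_model(ts$X, ts$duration_ms, ts$labels, cfg, seed = seed)
    save_model(m, file.path(out_dir, "model.json"))
  } else {
    m <- load_model(model)
  }
  mv$class <- NA_character_
  mv$class[ft$ok] <- classify(m, ft$X[ft$ok, , drop = FALSE], ft$dur[ft$ok])
  write_stage_csv(mv, file.path(out_dir, "movements_classified.csv"))
  sum(!is.na(mv$class))
}

# label detected movements by the overlapping ground-truth event; tracked
# larva ids are seeded arbitrarily per well, so they are first mapped to
# ground-truth larvae by frame-1 position
match_truth_labels <- function(mv, truth, tr) {
  ev <- truth$events
  core1 <- truth$core[1, , , drop = FALSE]     # 1 x 2 x gt-larvae
  lab <- rep(NA_character_, nrow(mv))
  for (w in unique(mv$well)) {
    gt_idx <- which(truth$well == w)
    tr1 <- tr[tr$well == w & tr$frame == 1, ]
    for (l in unique(mv$larva[mv$well == w])) {
      p <- unlist(tr1[tr1$larva == l, c("x", "y")])
      if (!length(gt_idx) || anyNA(p)) next
      g <- gt_idx[which.min(vapply(gt_idx, function(gg)
        sum((core1[1, , gg] - p)^2), 0))]
      rows <- which(mv$well == w & mv$larva == l)
      for (k in rows) {
        sel <- ev$larva == g & ev$start_frame <= mv$end_frame[k] &
          ev$end_frame >= mv$start_frame[k]
        if (any(sel)) lab[k] <- ev$class[which(sel)[1]]
      }
    }
  }
  lab
}

stage_interact <- function(out_dir, cfg) {
  mv <- read_stage_csv(file.path(out_dir, "movements_classified.csv"),
                       "classify")
  tr <- read_stage_csv(file.path(out_dir, "track.csv"), "track")
  mv <- mv[!is.na(mv$class), , drop = FALSE]
  if (!nrow(mv)) stop("no classified movements to analyse", call. = FALSE)
  mv$onset_s <- mv$start_s
  pos <- t(vapply(seq_len(nrow(mv)), function(k) {
    a <- tr[tr$well == mv$well[k] & tr$larva == mv$larva[k] &
              tr$frame == mv$start_frame[k], ]
    c(a$x[1], a$y[1])
  }, numeric(2)))
  mv$x_mm <- pos[, 1] * cfg$pixel_size_mm
  mv$y_mm <- pos[, 2] * cfg$pixel_size_mm
  res <- list()
  for (v in c("all", "same", "different"))
    res[[v]] <- transition_index(mv, v)
  long <- do.call(rbind, lapply(names(res), function(v) {
    I <- res[[v]]$I
    data.frame(variant = v,
               b1 = rep(rownames(I), 3), b2 = rep(colnames(I), each = 3),
               I = as.vector(I), n_pairs = as.vector(res[[v]]$counts))
  }))
  write_stage_csv(long, file.path(out_dir, "transitions.csv"))
  jsonlite::write_json(
    list(marginal = as.list(res$all$marginal),
         n_movements = nrow(mv),
         n_pairs = lapply(res, `[[`, "n_pairs")),
    file.path(out_dir, "transitions_summary.json"),
    digits = NA, auto_unbox = TRUE)
  nrow(long)
}
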