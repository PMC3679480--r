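#' Track all larvae in one well across frames
#'
#' Runs the full per-well tracking chain: static background estimation
#' (pixel-wise maximum), per-frame binarization and double erosion, core
#' candidate extraction, identity assignment by constant-velocity
#' prediction, collision resolution (repeated erosion of merged cores;
#' line or intensity separation of merged full bodies), heading from
#' image moments, and tail-tip / midline / bend-angle extraction. Frames
#' where the tail fails validation keep the previous frame's tail.
#'
#' @param frames List of full-frame intensity matrices, or a
#'   `larva_video`.
#' @param roi One well ROI (a one-row data.frame with `cx`, `cy`, `r`),
#'   or `NULL` to use the whole frame.
#' @param cfg A [larva_config()].
#' @param n_larvae Number of larvae in the well; `NULL` to take the
#'   count of core candidates in the first frame.
#' @param background Optional explicit background matrix (full frame
#'   size); by default the pixel-wise maximum over all frames. Supplying
#'   it is useful for short clips in which a larva never vacates its
#'   resting pixels.
#' @return A `larva_tracks` object: `core` (frames x 2 x larvae, full
#'   frame coordinates), `heading` (frames x larvae, rad), `valid`
#'   (frames x larvae), `bend_deg` (raw per-frame bend angle),
#'   `tail_valid`, `midline` (10 x 2 x frames x larvae), `tip`
#'   (frames x 2 x larvae), `eroded_change` (frames x larvae pixel-change
#'   counts between consecutive eroded masks), `collisions` (data.frame
#'   `frame`, `a`, `b`, `method`), `n_frames`, `cfg`, `well`.
#' @export
track_well <- function(frames, roi = NULL, cfg = larva_config(),
                       n_larvae = NULL, background = NULL) {
  if (inherits(frames, "larva_video")) frames <- frames$frames
  stopifnot(length(frames) >= 2)
  n <- length(frames)
  crop <- make_crop(frames[[1]], roi)
  bg <- if (is.null(background)) estimate_background(frames, roi)
        else crop(background)
  x_off <- attr(crop(frames[[1]]), "x_off") %||% 0L
  y_off <- attr(crop(frames[[1]]), "y_off") %||% 0L

  seg1 <- segment_cores(crop(frames[[1]]), bg, cfg)
  if (is.null(n_larvae)) n_larvae <- length(seg1$cores)
  if (n_larvae < 1) stop("no larva core found in the first frame", call. = FALSE)
  if (length(seg1$cores) != n_larvae)
    stop("first frame has ", length(seg1$cores), " core candidate(s), expected ",
         n_larvae, call. = FALSE)

  core <- array(NA_real_, c(n, 2, n_larvae))
  heading <- matrix(NA_real_, n, n_larvae)
  valid <- matrix(FALSE, n, n_larvae)
  bend <- matrix(NA_real_, n, n_larvae)
  tail_valid <- matrix(FALSE, n, n_larvae)
  midline <- array(NA_real_, c(10, 2, n, n_larvae))
  tip <- array(NA_real_, c(n, 2, n_larvae))
  er_change <- matrix(NA_real_, n, n_larvae)
  collisions <- data.frame(frame = integer(0), a = integer(0),
                           b = integer(0), stage = character(0),
                           method = character(0))
  prev_eroded_px <- vector("list", n_larvae)

  state <- list(pos = NULL, pos2 = NULL, heading = rep(NA_real_, n_larvae))

  for (i in seq_len(n)) {
    f <- crop(frames[[i]])
    seg <- if (i == 1) seg1 else segment_cores(f, bg, cfg)
    cand <- seg$cores
    larva_pix <- vector("list", n_larvae)   # eroded core pixels per larva

    if (i == 1) {
      # arbitrary seeding: candidates in label order
      for (j in seq_len(n_larvae)) {
        core[i, , j] <- cand[[j]]$centroid
        larva_pix[[j]] <- cand[[j]]$pixels
        valid[i, j] <- TRUE
      }
    } else {
      asg <- assign_identities(cand, state$pos, state$pos2)
      handled <- rep(FALSE, n_larvae)
      if (nrow(asg$collisions)) {
        for (r in seq_len(nrow(asg$collisions))) {
          a <- asg$collisions$a[r]; b <- asg$collisions$b[r]
          j <- asg$match[a]
          if (is.na(j)) j <- asg$match[b]
          method <- "unresolved"
          if (!is.na(j)) {
            sub <- seg$labels == cand[[j]]$label
            res <- resolve_merged_cores(sub)
            if (res$resolved) {
              cent <- res$centroids[1:2, , drop = FALSE]
              # assign the two split centroids by predicted distance
              d11 <- pt_dist(cent[1, ], asg$pred[a, ]) + pt_dist(cent[2, ], asg$pred[b, ])
              d12 <- pt_dist(cent[2, ], asg$pred[a, ]) + pt_dist(cent[1, ], asg$pred[b, ])
              if (d12 < d11) cent <- cent[2:1, , drop = FALSE]
              core[i, , a] <- cent[1, ]; core[i, , b] <- cent[2, ]
              valid[i, a] <- TRUE; valid[i, b] <- TRUE
              method <- "erosion"
            }
          }
          if (method == "unresolved") {
            # carry the constant-velocity prediction; core not measured
            core[i, , a] <- asg$pred[a, ]
            core[i, , b] <- asg$pred[b, ]
          }
          collisions <- rbind(collisions, data.frame(
            frame = i, a = a, b = b, stage = "core", method = method))
          handled[a] <- TRUE; handled[b] <- TRUE
        }
      }
      for (j in seq_len(n_larvae)) {
        if (handled[j]) next
        if (asg$valid[j]) {
          k <- asg$match[j]
          core[i, , j] <- cand[[k]]$centroid
          larva_pix[[j]] <- cand[[k]]$pixels
          valid[i, j] <- TRUE
        } else {
          core[i, , j] <- core[i - 1, , j]
          valid[i, j] <- FALSE
        }
      }
    }

    # headings
    for (j in seq_len(n_larvae)) {
      if (valid[i, j] && !is.null(larva_pix[[j]]) && nrow(larva_pix[[j]]) >= 3) {
        w <- seg$diff[larva_pix[[j]]]
        heading[i, j] <- as.numeric(
          compute_heading(larva_pix[[j]], w, prev_heading = state$heading[j]))
      } else {
        heading[i, j] <- if (i > 1) heading[i - 1, j] else 0
      }
    }

    # eroded-image pixel change per larva (motion evidence)
    for (j in seq_len(n_larvae)) {
      if (!is.null(larva_pix[[j]])) {
        cur <- complex(real = larva_pix[[j]][, 1],
                       imaginary = larva_pix[[j]][, 2])
        prv <- prev_eroded_px[[j]]
        if (!is.null(prv)) {
          # symmetric difference of the two eroded pixel sets
          er_change[i, j] <- length(union(cur, prv)) - length(intersect(cur, prv))
        }
        prev_eroded_px[[j]] <- cur
      }
    }

    # full bodies and tails
    labels_pre <- NULL
    bodies <- vector("list", n_larvae)
    body_label_of <- rep(NA_integer_, n_larvae)
    for (j in seq_len(n_larvae)) {
      if (anyNA(core[i, , j])) next
      if (is.null(labels_pre)) {
        labels_pre <- label_components(seg$binary)
        attr(labels_pre, "labelled") <- TRUE
      }
      b <- tryCatch(extract_full_body(labels_pre, core[i, , j]),
                    error = function(e) NULL)
      bodies[[j]] <- b
      if (!is.null(b)) body_label_of[j] <- b$label
    }
    # split merged full bodies (pairwise)
    for (j in seq_len(n_larvae)) {
      b <- bodies[[j]]
      if (is.null(b)) next
      others <- which(body_label_of == b$label)
      if (length(others) == 2 && b$area > cfg$contact_area_px2 &&
          j == min(others)) {
        a <- others[1]; bb <- others[2]
        heads <- rbind(core[i, , a], core[i, , bb])
        sep <- tryCatch(
          separate_bodies(b, heads, seg$diff, cfg),
          error = function(e) list(resolved = FALSE, method = "unresolved"))
        collisions <- rbind(collisions, data.frame(
          frame = i, a = a, b = bb, stage = "body", method = sep$method))
        if (sep$resolved) {
          bodies[[a]] <- body_from_pixels(sep$components[[1]], dim(seg$binary))
          bodies[[bb]] <- body_from_pixels(sep$components[[2]], dim(seg$binary))
        } else {
          bodies[a] <- list(NULL); bodies[bb] <- list(NULL)
        }
      } else if (length(others) > 2 && j == min(others)) {
        # more than two larvae in one component: not separated
        for (o in others) bodies[o] <- list(NULL)
        collisions <- rbind(collisions, data.frame(
          frame = i, a = others[1], b = others[2], stage = "body",
          method = "unresolved"))
      }
    }
    for (j in seq_len(n_larvae)) {
      ok <- FALSE
      b <- bodies[[j]]
      if (!is.null(b) && !is.na(heading[i, j])) {
        hd <- heading[i, j]
        tp <- find_tail_tip(b, core[i, , j], hd, cfg)
        if (!is.null(tp)) {
          h_origin <- core[i, , j] - cfg$head_radius_px * c(cos(hd), sin(hd))
          ml <- compute_midline(tp, h_origin, cfg)
          if (ml$valid) {
            midline[, , i, j] <- ml$points
            tip[i, , j] <- ml$points[10, ]
            bend[i, j] <- compute_bend_angle(ml, hd)
            ok <- TRUE
          }
        }
      }
      if (!ok && i > 1) {
        # tail set to the previous frame
        midline[, , i, j] <- midline[, , i - 1, j]
        tip[i, , j] <- tip[i - 1, , j]
        bend[i, j] <- bend[i - 1, j]
      }
      tail_valid[i, j] <- ok
    }

    state$pos2 <- state$pos
    state$pos <- t(core[i, , , drop = FALSE][1, , ])
    if (n_larvae == 1) state$pos <- matrix(core[i, , 1], 1, 2)
    state$heading <- heading[i, ]
  }

  # map back to full-frame coordinates
  core[, 1, ] <- core[, 1, ] + x_off
  core[, 2, ] <- core[, 2, ] + y_off
  midline[, 1, , ] <- midline[, 1, , ] + x_off
  midline[, 2, , ] <- midline[, 2, , ] + y_off
  tip[, 1, ] <- tip[, 1, ] + x_off
  tip[, 2, ] <- tip[, 2, ] + y_off

  structure(list(core = core, heading = heading, valid = valid,
                 bend_deg = bend, tail_valid = tail_valid,
                 midline = midline, tip = tip, eroded_change = er_change,
                 collisions = collisions, n_frames = n, n_larvae = n_larvae,
                 cfg = cfg, well = roi, background = bg),
            class = "larva_tracks")
}

body_from_pixels <- function(pixels, dims) {
  m <- matrix(0L, dims[1], dims[2])
  m[pixels] <- 1L
  lab <- label_components(m)
  attr(lab, "labelled") <- TRUE
  structure(list(pixels = pixels, label = lab[pixels[1, 1], pixels[1, 2]],
                 labels = lab, area = nrow(pixels)), class = "full_body")
}

#' Track a whole multi-well video
#'
#' Detects the wells (unless given) and runs [track_well()] on each.
#'
#' @param frames List of frames or a `larva_video`.
#' @param cfg A [larva_config()].
#' @param wells Data.frame of well ROIs, or `NULL` to detect
#'   `expected_wells` wells in the first frame.
#' @param expected_wells Number of wells to detect when `wells` is `NULL`.
#' @param n_larvae Per-well larva count (recycled), or `NULL` to infer.
#' @return A list of `larva_tracks`, one per well.
#' @export
track_video <- function(frames, cfg = larva_config(), wells = NULL,
                        expected_wells = 1, n_larvae = NULL,
                        background = NULL) {
  if (inherits(frames, "larva_video")) {
    if (is.null(wells)) wells <- frames$wells
    frames <- frames$frames
  }
  if (is.null(wells))
    wells <- detect_wells(frames[[1]], expected_wells)
  n_larvae <- if (is.null(n_larvae)) rep(list(NULL), nrow(wells))
              else as.list(rep(n_larvae, length.out = nrow(wells)))
  out <- vector("list", nrow(wells))
  for (k in seq_len(nrow(wells)))
    out[[k]] <- track_well(frames, wells[k, ], cfg, n_larvae[[k]],
                           background = background)
  out
}

#' Cleaned bend-angle traces of tracked larvae
#'
#' @param tracks A `larva_tracks` object.
#' @return Matrix frames x larvae of cleaned bend angles (deg): invalid
#'   frames filled from the previous valid frame, then median-filtered.
#' @export
bend_traces <- function(tracks) {
  stopifnot(inherits(tracks, "larva_tracks"))
  out <- matrix(NA_real_, tracks$n_frames, tracks$n_larvae)
  for (j in seq_len(tracks$n_larvae))
    out[, j] <- clean_trace(tracks$bend_deg[, j],
                            !is.na(tracks$bend_deg[, j]), tracks$cfg)
  out
}

#' @export
print.larva_tracks <- function(x, ...) {
  cat(sprintf("<larva_tracks> %d frames, %d larva(e); tail valid %.1f%%; %d collision record(s)\n",
              x$n_frames, x$n_larvae, 100 * mean(x$tail_valid),
              nrow(x$collisions)))
  invisible(x)
}
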