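#' Well layout for synthetic videos
#'
#' @param n_wells Number of circular wells.
#' @param radius_px Well radius in pixels.
#' @param margin_px Margin between wells and around the image border.
#' @param ncol Number of well columns (default: near-square grid).
#' @return A `well_layout` list with `wells` (data.frame `index`, `cx`,
#'   `cy`, `r`, row-major order) and the image `width` and `height`.
#' @export
well_layout <- function(n_wells = 1, radius_px = 150, margin_px = 20,
                        ncol = NULL) {
  stopifnot(n_wells >= 1, radius_px > 0)
  nc <- ncol %||% ceiling(sqrt(n_wells))
  nr <- ceiling(n_wells / nc)
  pitch <- 2 * radius_px + margin_px
  idx <- seq_len(n_wells) - 1L
  row <- idx %/% nc
  col <- idx %% nc
  wells <- data.frame(index = idx + 1L,
                      cx = margin_px + radius_px + col * pitch,
                      cy = margin_px + radius_px + row * pitch,
                      r = radius_px)
  structure(list(wells = wells,
                 width = as.integer(margin_px + nc * pitch),
                 height = as.integer(margin_px + nr * pitch)),
            class = "well_layout")
}

#' Script one larva for the synthetic renderer
#'
#' Motion is either event-driven (the larva translates and turns during
#' scheduled maneuvers and rests between them) or follows an explicit
#' per-frame `path`, in which case scheduled events still drive the tail
#' bend but not locomotion.
#'
#' @param well Well index the larva lives in.
#' @param x,y Initial core position (px, image coordinates).
#' @param heading_deg Initial heading (deg, 0 = +x, measured toward +y).
#' @param events A data.frame with columns `start_ms`, `class` and
#'   optionally `turn_sign` (+1 left-to-right sign of the maneuver), or an
#'   empty data.frame / `NULL` for a resting larva.
#' @param path Optional n_frames x 3 matrix (`x`, `y`, `heading_deg`)
#'   overriding locomotion.
#' @return A `larva_script` list.
#' @export
larva_script <- function(well = 1, x = NULL, y = NULL, heading_deg = 0,
                         events = NULL, path = NULL) {
  if (is.null(events))
    events <- data.frame(start_ms = numeric(0), class = character(0))
  if (is.null(path) && (is.null(x) || is.null(y)))
    stop("either an initial position (x, y) or a path is required",
         call. = FALSE)
  structure(list(well = well, x = x, y = y,
                 heading_rad = deg2rad(heading_deg),
                 events = events, path = path),
            class = "larva_script")
}

# Body geometry constants (px at default calibration). The head is a
# tapered capsule (wider at the snout) so that the orientation and the
# head/tail polarity are recoverable from second- and third-order moments
# of the eroded core; the tail is a polyline of linearly decreasing
# thickness thin enough to be removed entirely by the double erosion.
.body <- list(
  head_half_span = 4.5,   # capsule axis half-length
  head_r_front = 5.5,     # capsule radius at the snout
  head_r_rear = 4.0,      # capsule radius at the trunk
  tail_arc_px = 45,       # tail arc length from trunk attachment to tip
  tail_r_base = 1.6,      # tail thickness radius at the trunk
  tail_r_tip = 0.7,       # tail thickness radius at the tip
  head_value = 50,        # rendered intensity of the head (0-255)
  tail_value_base = 70,   # tail intensity at the trunk ...
  tail_value_tip = 110,   # ... ramping lighter toward the tip
  well_value = 230,       # well interior background
  outside_value = 110     # background outside the wells
)

# axial offset of the head-blob centroid from the capsule centre,
# computed once by fine rasterization of the continuum shape
head_centroid_offset <- function() {
  if (!is.null(.body_cache$delta)) return(.body_cache$delta)
  h <- .body$head_half_span
  rmax <- .body$head_r_front
  g <- seq(-(h + rmax + 1), h + rmax + 1, by = 0.1)
  pts <- expand.grid(s = g, q = g)
  sc <- pmin(pmax(pts$s, -h), h)
  r <- .body$head_r_front * (sc + h) / (2 * h) +
       .body$head_r_rear * (h - sc) / (2 * h)
  inside <- (pts$s - sc)^2 + pts$q^2 <= r^2
  delta <- mean(pts$s[inside])
  .body_cache$delta <- delta
  delta
}
.body_cache <- new.env(parent = emptyenv())

# per-frame (x, y, heading) states of one larva from its script
simulate_larva_states <- function(script, n_frames, fps, mm_per_px = 0.066) {
  if (!is.null(script$path)) {
    p <- script$path
    stopifnot(nrow(p) == n_frames)
    return(list(pos = cbind(p[, 1], p[, 2]),
                heading = deg2rad(p[, 3]),
                ev = script_events(script, n_frames, fps)))
  }
  ev <- script_events(script, n_frames, fps)
  pos <- matrix(0, n_frames, 2)
  heading <- numeric(n_frames)
  pos[1, ] <- c(script$x, script$y)
  heading[1] <- script$heading_rad
  dt <- 1 / fps
  for (i in seq_len(n_frames)) {
    t_ms <- (i - 1) * 1000 / fps
    k <- active_event(ev, t_ms)
    if (i > 1) {
      pos[i, ] <- pos[i - 1, ]
      heading[i] <- heading[i - 1]
    }
    if (k > 0) {
      if (is.na(ev$h0[k])) ev$h0[k] <- heading[i]
      arch <- ev$archetype[[k]]
      u <- (t_ms - ev$start_ms[k]) / arch$duration_ms
      # smoothstep heading ramp; translation along the current heading
      heading[i] <- ev$h0[k] + ev$turn_sign[k] *
        deg2rad(arch$heading_change_deg) * (3 * u^2 - 2 * u^3)
      sp <- archetype_speed(arch, t_ms - ev$start_ms[k])
      pos[i, ] <- pos[i, ] + sp * dt / mm_per_px *
        c(cos(heading[i]), sin(heading[i]))
    }
  }
  list(pos = pos, heading = heading, ev = ev)
}

script_events <- function(script, n_frames, fps) {
  e <- script$events
  if (!nrow(e))
    return(data.frame(start_ms = numeric(0), turn_sign = numeric(0),
                      h0 = numeric(0), bend_sign = numeric(0),
                      archetype = I(list())))
  archs <- lapply(seq_len(nrow(e)), function(i) {
    if (!is.null(e$archetype)) e$archetype[[i]]
    else maneuver_archetype(e$class[i])
  })
  ts <- if (!is.null(e$turn_sign)) e$turn_sign else sample(c(-1, 1), nrow(e), TRUE)
  ends <- e$start_ms + vapply(archs, `[[`, 0, "duration_ms")
  o <- order(e$start_ms)
  if (any(e$start_ms[o][-1] < ends[o][-length(o)]))
    stop("scheduled events overlap", call. = FALSE)
  data.frame(start_ms = e$start_ms, turn_sign = ts, h0 = NA_real_,
             bend_sign = ts, archetype = I(archs))
}

active_event <- function(ev, t_ms) {
  if (!nrow(ev)) return(0L)
  for (k in seq_len(nrow(ev))) {
    if (t_ms >= ev$start_ms[k] &&
        t_ms <= ev$start_ms[k] + ev$archetype[[k]]$duration_ms)
      return(k)
  }
  0L
}

# fine midline of the tail for a given drive bend angle (deg): a polyline
# starting at the trunk attachment, initial tangent pointing tailward,
# accumulating a total turn of 2 * alpha with a curvature profile that is
# either uniform or concentrated caudally
tail_fine_midline <- function(core, heading, alpha_deg, profile = "uniform",
                              n = 46) {
  L <- .body$tail_arc_px
  ds <- L / (n - 1)
  s_rel <- seq(0, 1, length.out = n)
  w <- if (profile == "caudal") 3 * s_rel^2 else rep(1, n)
  W <- cumsum(w) - w[1]
  W <- if (max(W) > 0) W / max(W) else W
  phi <- heading + pi + 2 * deg2rad(alpha_deg) * W
  p0 <- core + .body$head_half_span * c(-cos(heading), -sin(heading))
  x <- p0[1] + c(0, cumsum(cos(phi[-1]) * ds))
  y <- p0[2] + c(0, cumsum(sin(phi[-1]) * ds))
  cbind(x, y)
}

# stamp an anti-aliased dark disk into a patch matrix whose first pixel is
# at image coordinates (x0, y0) (darkest wins)
stamp_disk_patch <- function(patch, x0, y0, cx, cy, r, value) {
  xr <- max(1L, floor(cx - r - 1) - x0 + 1L):
    min(nrow(patch), ceiling(cx + r + 1) - x0 + 1L)
  yr <- max(1L, floor(cy - r - 1) - y0 + 1L):
    min(ncol(patch), ceiling(cy + r + 1) - y0 + 1L)
  d <- sqrt(outer((xr + x0 - 1 - cx)^2, (yr + y0 - 1 - cy)^2, `+`))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  p <- patch[xr, yr]
  patch[xr, yr] <- pmin(p, p * (1 - cov) + value * cov)
  patch
}

stamp_larva <- function(img, core, heading, midline_fine) {
  b <- .body
  ns <- 10
  s <- seq(-b$head_half_span, b$head_half_span, length.out = ns)
  hx <- core[1] + s * cos(heading); hy <- core[2] + s * sin(heading)
  hr <- b$head_r_rear + (b$head_r_front - b$head_r_rear) *
    (s + b$head_half_span) / (2 * b$head_half_span)
  n <- nrow(midline_fine)
  fr <- seq(0, 1, length.out = n)
  cx <- c(hx, midline_fine[, 1]); cy <- c(hy, midline_fine[, 2])
  rr <- c(hr, b$tail_r_base + (b$tail_r_tip - b$tail_r_base) * fr)
  vv <- c(rep(b$head_value, ns),
          b$tail_value_base + (b$tail_value_tip - b$tail_value_base) * fr)
  # one local patch covering the whole body, stamped disk by disk
  x0 <- max(1L, floor(min(cx - rr)) - 1L)
  x1 <- min(nrow(img), ceiling(max(cx + rr)) + 1L)
  y0 <- max(1L, floor(min(cy - rr)) - 1L)
  y1 <- min(ncol(img), ceiling(max(cy + rr)) + 1L)
  patch <- img[x0:x1, y0:y1, drop = FALSE]
  for (i in seq_along(cx))
    patch <- stamp_disk_patch(patch, x0, y0, cx[i], cy[i], rr[i], vv[i])
  img[x0:x1, y0:y1] <- patch
  img
}

#' Render a synthetic multi-larva well video with exact ground truth
#'
#' Produces a stack of grayscale frames (bright circular wells on a darker
#' surround, dark larvae) together with per-frame ground truth: core
#' position, heading, 10-point tail midline, signed bend angle, and the
#' scheduled maneuver boundaries and class labels. The output is
#' deterministic given the seed.
#'
#' @param layout A [well_layout()].
#' @param larvae List of [larva_script()]s.
#' @param n_frames Number of frames.
#' @param cfg A [larva_config()].
#' @param seed Integer seed (event signs, pixel noise).
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity
#'   levels on 0-255; 0 disables noise).
#' @return A `larva_video` list: `frames` (list of integer width x height
#'   matrices, dim1 = x), `width`, `height`, `wells`, `cfg`, and `truth`
#'   with elements `core` (frames x 2 x larvae), `heading` (rad),
#'   `bend_deg`, `tip` (frames x 2 x larvae), `midline`
#'   (10 x 2 x frames x larvae), `events` (data.frame `larva`,
#'   `start_frame`, `end_frame`, `class`), and `well` (per-larva index).
#' @export
render_video <- function(layout, larvae, n_frames, cfg = larva_config(),
                         seed = 1, noise_sd = 2) {
  stopifnot(inherits(layout, "well_layout"), n_frames >= 1)
  wells <- layout$wells
  fps <- cfg$frame_rate_hz
  nl <- length(larvae)
  with_seed(seed, {
    for (sc in larvae) {
      w <- wells[wells$index == sc$well, ]
      if (!nrow(w)) stop("larva assigned to unknown well ", sc$well, call. = FALSE)
      x0 <- if (!is.null(sc$path)) sc$path[1, 1] else sc$x
      y0 <- if (!is.null(sc$path)) sc$path[1, 2] else sc$y
      if (pt_dist(c(x0, y0), c(w$cx, w$cy)) > w$r - 10)
        stop("larva placed outside its well", call. = FALSE)
    }
    states <- lapply(larvae, simulate_larva_states, n_frames = n_frames,
                     fps = fps, mm_per_px = cfg$pixel_size_mm)
    # base image: darker surround, bright well disks
    base <- matrix(.body$outside_value, layout$width, layout$height)
    for (k in seq_len(nrow(wells))) {
      xr <- seq_len(layout$width); yr <- seq_len(layout$height)
      d <- sqrt(outer((xr - wells$cx[k])^2, (yr - wells$cy[k])^2, `+`))
      cov <- pmin(pmax(wells$r[k] + 0.5 - d, 0), 1)
      base <- base * (1 - cov) + .body$well_value * cov
    }
    delta <- head_centroid_offset()
    truth <- list(core = array(NA_real_, c(n_frames, 2, nl)),
                  heading = matrix(NA_real_, n_frames, nl),
                  bend_deg = matrix(NA_real_, n_frames, nl),
                  tip = array(NA_real_, c(n_frames, 2, nl)),
                  midline = array(NA_real_, c(10, 2, n_frames, nl)),
                  well = vapply(larvae, `[[`, 0, "well"))
    events <- NULL
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      img <- base
      t_ms <- (i - 1) * 1000 / fps
      for (j in seq_len(nl)) {
        st <- states[[j]]
        core <- st$pos[i, ]; hd <- st$heading[i]
        k <- active_event(st$ev, t_ms)
        alpha <- if (k > 0) {
          arch <- st$ev$archetype[[k]]
          archetype_bend(arch, t_ms - st$ev$start_ms[k],
                         sign = st$ev$bend_sign[k])
        } else 0
        prof <- if (k > 0) st$ev$archetype[[k]]$curvature_profile else "uniform"
        fine <- tail_fine_midline(core, hd, alpha, prof)
        img <- stamp_larva(img, core, hd, fine)
        # ground truth: head-blob centroid, geometric bend angle, 10-point
        # midline starting one head radius behind the core centre
        gc <- core + delta * c(cos(hd), sin(hd))
        truth$core[i, , j] <- gc
        truth$heading[i, j] <- wrap_2pi(hd)
        h_origin <- gc - cfg$head_radius_px * c(cos(hd), sin(hd))
        tip <- fine[nrow(fine), ]
        truth$tip[i, , j] <- tip
        truth$bend_deg[i, j] <- rad2deg(
          signed_angle(c(-cos(hd), -sin(hd)), tip - h_origin))
        # keep only the tail path caudal to the head origin so the
        # midline does not double back on itself
        proj <- (fine[, 1] - h_origin[1]) * (-cos(hd)) +
                (fine[, 2] - h_origin[2]) * (-sin(hd))
        ml <- resample_polyline(rbind(h_origin, fine[proj > 0, , drop = FALSE]),
                                10)
        truth$midline[, , i, j] <- ml
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow(img), ncol(img))
      frames[[i]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                            nrow(img), ncol(img))
    }
    for (j in seq_len(nl)) {
      ev <- states[[j]]$ev
      if (nrow(ev)) {
        durs <- vapply(ev$archetype, `[[`, 0, "duration_ms")
        cls <- vapply(ev$archetype, `[[`, "", "class")
        events <- rbind(events, data.frame(
          larva = j,
          start_frame = pmax(1L, floor(ev$start_ms * fps / 1000) + 1L),
          end_frame = pmin(n_frames, as.integer(ceiling((ev$start_ms + durs) * fps / 1000))),
          class = cls, stringsAsFactors = FALSE))
      }
    }
    truth$events <- events %||%
      data.frame(larva = integer(0), start_frame = integer(0),
                 end_frame = integer(0), class = character(0))
    structure(list(frames = frames, width = layout$width,
                   height = layout$height, wells = wells, cfg = cfg,
                   truth = truth, seed = seed, noise_sd = noise_sd),
              class = "larva_video")
  })
}

#' @export
print.larva_video <- function(x, ...) {
  cat(sprintf("<larva_video> %d frames, %dx%d px, %d well(s), %d larva(e)\n",
              length(x$frames), x$width, x$height, nrow(x$wells),
              dim(x$truth$core)[3]))
  invisible(x)
}
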