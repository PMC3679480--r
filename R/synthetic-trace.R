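#' Maneuver archetypes for synthetic data
#'
#' Defines the stereotypical kinematic envelope of the three maneuver
#' classes observed in groups of 5-7 dpf zebrafish larvae: slow forward
#' swims (`"S"`, low-amplitude caudally-confined bending, little heading
#' change), routine turns (`"T"`, large initial bend, slow left-right
#' alternation) and escapes (`"E"`, large bend, fast alternation and high
#' translation speed). The class defaults differ mainly in bend amplitude,
#' alternation frequency, translation speed and heading change, which is
#' what separates them in the classifier's feature space.
#'
#' @param class One of `"S"`, `"T"`, `"E"`.
#' @param amplitude_deg Peak tail-bending angle amplitude (deg).
#' @param freq_hz Left-right alternation (tail-beat) frequency (Hz).
#' @param duration_ms Duration of the maneuver (ms).
#' @param heading_change_deg Net heading change over the maneuver (deg).
#' @param peak_speed_mm_s Peak translation speed of the core (mm/s).
#' @param curvature_profile `"caudal"` (bending confined to the caudal
#'   tail, slow swims) or `"uniform"` (bending distributed head to tail,
#'   turns and escapes).
#' @param damping_ms Exponential decay time of the bend envelope (ms).
#' @return A `maneuver_archetype` object (named list).
#' @export
maneuver_archetype <- function(class = c("S", "T", "E"),
                               amplitude_deg = NULL,
                               freq_hz = NULL,
                               duration_ms = NULL,
                               heading_change_deg = NULL,
                               peak_speed_mm_s = NULL,
                               curvature_profile = NULL,
                               damping_ms = NULL) {
  class <- match.arg(class)
  def <- switch(class,
    S = list(amplitude_deg = 15, freq_hz = 24, duration_ms = 200,
             heading_change_deg = 5, peak_speed_mm_s = 8,
             curvature_profile = "caudal", damping_ms = 150),
    T = list(amplitude_deg = 60, freq_hz = 15, duration_ms = 250,
             heading_change_deg = 45, peak_speed_mm_s = 10,
             curvature_profile = "uniform", damping_ms = 180),
    E = list(amplitude_deg = 85, freq_hz = 35, duration_ms = 170,
             heading_change_deg = 80, peak_speed_mm_s = 35,
             curvature_profile = "uniform", damping_ms = 120))
  a <- list(class = class,
            amplitude_deg = amplitude_deg %||% def$amplitude_deg,
            freq_hz = freq_hz %||% def$freq_hz,
            duration_ms = duration_ms %||% def$duration_ms,
            heading_change_deg = heading_change_deg %||% def$heading_change_deg,
            peak_speed_mm_s = peak_speed_mm_s %||% def$peak_speed_mm_s,
            curvature_profile = curvature_profile %||% def$curvature_profile,
            damping_ms = damping_ms %||% def$damping_ms)
  stopifnot(a$amplitude_deg > 0, a$freq_hz > 0, a$duration_ms > 0,
            a$curvature_profile %in% c("caudal", "uniform"))
  structure(a, class = c("maneuver_archetype", "list"))
}

# bend angle (deg) of an archetype at times t_ms since maneuver onset:
# damped sinusoid starting at 0 (continuous onset) with a raised-cosine
# release over the last 15% of the maneuver, so the tail returns to rest
# instead of freezing mid-bend
archetype_bend <- function(arch, t_ms, sign = 1) {
  d <- arch$duration_ms
  rel_ms <- min(15, 0.15 * d)    # ~muscle relaxation at the end of a bout
  v <- (t_ms - (d - rel_ms)) / rel_ms
  release <- ifelse(v < 0, 1, 0.5 * (1 + cos(pi * pmin(v, 1))))
  ifelse(t_ms < 0 | t_ms > d, 0,
         sign * arch$amplitude_deg * release *
           exp(-t_ms / arch$damping_ms) *
           sin(2 * pi * arch$freq_hz * t_ms / 1000))
}

# translation speed (mm/s) at t_ms since onset: smooth sin^2 envelope
archetype_speed <- function(arch, t_ms) {
  ifelse(t_ms < 0 | t_ms > arch$duration_ms, 0,
         arch$peak_speed_mm_s * sin(pi * t_ms / arch$duration_ms)^2)
}

#' Generate a synthetic bend-angle trace with exact ground truth
#'
#' Builds a tail-bending-angle time series from a baseline of zero plus one
#' damped-oscillation segment per scheduled maneuver, plus i.i.d. Gaussian
#' noise. The scheduled event boundaries are returned exactly, so movement
#' detection can be scored against ground truth.
#'
#' @param schedule A data.frame with columns `start_ms` and `class`
#'   (`"S"`/`"T"`/`"E"`), or a list of `list(start_ms =, archetype =)`
#'   entries for custom archetypes.
#' @param duration_ms Total trace duration (ms).
#' @param noise_sd_deg Standard deviation of the additive Gaussian noise
#'   (deg).
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @param cfg A [larva_config()]; supplies the frame rate.
#' @param first_bend_sign `"random"` (default), `1` or `-1`: side of the
#'   first bend of each maneuver.
#' @return A list with `angle_deg` (per-frame trace), `valid` (all `TRUE`),
#'   `frame_rate_hz`, and `events`: a data.frame of ground-truth events
#'   (`start_frame`, `end_frame`, 1-based inclusive, and `class`).
#' @export
synth_bend_trace <- function(schedule, duration_ms, noise_sd_deg = 0,
                             seed = 1, cfg = larva_config(),
                             first_bend_sign = "random") {
  sched <- normalize_schedule(schedule)
  fps <- cfg$frame_rate_hz
  n <- max(1L, floor(duration_ms * fps / 1000))
  t_ms <- (seq_len(n) - 1) * 1000 / fps
  if (nrow(sched)) {
    ends <- sched$start_ms + vapply(sched$archetype, function(a) a$duration_ms, 0)
    if (any(ends > duration_ms))
      stop("scheduled event extends beyond the trace duration", call. = FALSE)
    o <- order(sched$start_ms)
    if (any(sched$start_ms[o][-1] < ends[o][-nrow(sched)]))
      stop("scheduled events overlap", call. = FALSE)
  }
  with_seed(seed, {
    angle <- numeric(n)
    events <- data.frame(start_frame = integer(0), end_frame = integer(0),
                         class = character(0), stringsAsFactors = FALSE)
    if (nrow(sched)) for (i in seq_len(nrow(sched))) {
      arch <- sched$archetype[[i]]
      s <- if (identical(first_bend_sign, "random")) sample(c(-1, 1), 1) else first_bend_sign
      angle <- angle + archetype_bend(arch, t_ms - sched$start_ms[i], sign = s)
      sf <- max(1L, floor(sched$start_ms[i] * fps / 1000) + 1L)
      ef <- min(n, ceiling((sched$start_ms[i] + arch$duration_ms) * fps / 1000))
      events <- rbind(events, data.frame(start_frame = sf, end_frame = ef,
                                         class = arch$class,
                                         stringsAsFactors = FALSE))
    }
    if (noise_sd_deg > 0) angle <- angle + stats::rnorm(n, 0, noise_sd_deg)
    list(angle_deg = angle, valid = rep(TRUE, n), frame_rate_hz = fps,
         events = events[order(events$start_frame), , drop = FALSE])
  })
}

normalize_schedule <- function(schedule) {
  if (is.data.frame(schedule)) {
    if (!nrow(schedule))
      return(data.frame(start_ms = numeric(0),
                        archetype = I(list()), stringsAsFactors = FALSE))
    stopifnot(all(c("start_ms", "class") %in% names(schedule)))
    archs <- lapply(schedule$class, maneuver_archetype)
    return(data.frame(start_ms = schedule$start_ms,
                      archetype = I(archs), stringsAsFactors = FALSE))
  }
  if (is.list(schedule)) {
    if (!length(schedule))
      return(data.frame(start_ms = numeric(0),
                        archetype = I(list()), stringsAsFactors = FALSE))
    return(data.frame(
      start_ms = vapply(schedule, `[[`, 0, "start_ms"),
      archetype = I(lapply(schedule, `[[`, "archetype")),
      stringsAsFactors = FALSE))
  }
  stop("schedule must be a data.frame or a list", call. = FALSE)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
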