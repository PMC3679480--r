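# Feature grids (ms): 15 amplitude + 14 instantaneous-frequency +
# 14 cumulative-bend + 10 speed samples = 53 raw components.
.feature_grid <- list(
  amplitude = seq(0, 178 - 10, by = 12),       # 15 samples on [0, 178)
  frequency = seq(7, 104 - 6, by = 7),         # 14 samples on (0, 104)
  cumulative = seq(12, 178 - 10, by = 12),     # 14 samples on (0, 178)
  speed = seq(0, 240 - 24, by = 24)            # 10 samples on [0, 240)
)

#' Extract the dynamic feature vector of one movement
#'
#' Four time series are extracted from the bout, with time zero at the
#' peak of the first tail bend: the absolute bend-angle amplitude
#' (sampled on 0-178 ms in 12 ms bins), the instantaneous left-right
#' alternation frequency from successive bend extrema (0-104 ms, 7 ms
#' bins, held piecewise-constant between extrema), the cumulative bend
#' angle (running mean of the absolute angle from time zero; 0-178 ms,
#' 12 ms bins) and the core speed (0-240 ms, 24 ms bins). Series are
#' spline-interpolated onto their grids; samples beyond the end of the
#' bout take the last available value (flagged `padded`). The 53 raw
#' components are supplemented by the total bout duration.
#'
#' @param event One event row (`start_frame`, `end_frame`).
#' @param trace Cleaned full-trace bend angles (deg).
#' @param track n x 2 per-frame core positions (px), or `NULL` (speed
#'   features 0).
#' @param cfg A [larva_config()].
#' @return A `movement_features` list: `raw` (named numeric, length 53),
#'   `duration_ms`, `padded`.
#' @export
extract_features <- function(event, trace, track = NULL,
                             cfg = larva_config()) {
  idx <- event$start_frame:event$end_frame
  a <- trace[idx]
  fps <- cfg$frame_rate_hz
  ext <- local_extrema(a)
  ext <- ext[abs(a[ext]) > cfg$oscillation_min_deg]
  if (!length(ext))
    stop("feature-extraction: no bend extremum found in the movement",
         call. = FALSE)
  i0 <- ext[1]                       # peak of the first bend
  t_ms <- (seq_along(a) - i0) * 1000 / fps
  t_end <- t_ms[length(t_ms)]
  g <- .feature_grid
  padded <- t_end < max(g$amplitude, g$frequency, g$cumulative, g$speed)

  amp <- sample_series(t_ms, abs(a), g$amplitude)

  # instantaneous frequency: 1 / (2 * half-period) between successive
  # alternating extrema, piecewise constant
  freq <- rep(0, length(g$frequency))
  if (length(ext) >= 2) {
    s <- sign(a[ext])
    keep <- c(TRUE, s[-1] != s[-length(s)])
    ext_a <- ext[keep]
    if (length(ext_a) >= 2) {
      half <- diff(ext_a) / fps            # half-periods in s
      f_hz <- 1 / (2 * half)
      t_ext <- t_ms[ext_a]
      freq <- vapply(g$frequency, function(tq) {
        k <- findInterval(tq, t_ext[-1], left.open = FALSE) + 1L
        f_hz[min(max(k, 1L), length(f_hz))]
      }, 0)
    }
  }

  csum <- cumsum(abs(a))
  run_mean <- csum / seq_along(a)
  from0 <- t_ms >= 0
  cum0 <- cumsum(abs(a[from0])) / seq_len(sum(from0))
  cum_series <- c(run_mean[!from0], cum0)
  cum <- sample_series(t_ms, cum_series, g$cumulative)

  if (!is.null(track)) {
    steps <- sqrt(rowSums(diff(track[idx, , drop = FALSE])^2))
    spd <- c(steps[1], steps) * fps * cfg$pixel_size_mm   # mm/s
  } else spd <- rep(0, length(a))
  speed <- sample_series(t_ms, spd, g$speed)

  raw <- c(amp, freq, cum, speed)
  names(raw) <- c(paste0("amp_", g$amplitude), paste0("freq_", g$frequency),
                  paste0("cum_", g$cumulative), paste0("speed_", g$speed))
  structure(list(raw = raw,
                 duration_ms = length(a) * 1000 / fps,
                 padded = padded),
            class = "movement_features")
}

# spline interpolation within the observed range, last/first value beyond
sample_series <- function(t_ms, y, grid) {
  if (length(t_ms) < 4) {
    out <- stats::approx(t_ms, y, xout = pmin(pmax(grid, min(t_ms)), max(t_ms)),
                         rule = 2, ties = "ordered")$y
    return(out)
  }
  f <- stats::splinefun(t_ms, y, method = "natural")
  f(pmin(pmax(grid, min(t_ms)), max(t_ms)))
}

#' Feature matrix for a set of movements
#'
#' @param events Data.frame of events (rows passed to
#'   [extract_features()]).
#' @param trace,track,cfg As in [extract_features()].
#' @return A list with `X` (n x 53 matrix), `duration_ms`, `ok` (logical:
#'   rows where extraction succeeded).
#' @export
extract_feature_matrix <- function(events, trace, track = NULL,
                                   cfg = larva_config()) {
  n <- nrow(events)
  X <- matrix(NA_real_, n, 53)
  dur <- rep(NA_real_, n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    fv <- tryCatch(extract_features(events[k, ], trace, track, cfg),
                   error = function(e) NULL)
    if (!is.null(fv)) {
      X[k, ] <- fv$raw
      dur[k] <- fv$duration_ms
      ok[k] <- TRUE
    }
  }
  if (any(ok)) colnames(X) <- names(.feature_grid_names())
  list(X = X, duration_ms = dur, ok = ok)
}

.feature_grid_names <- function() {
  g <- .feature_grid
  stats::setNames(seq_len(53),
                  c(paste0("amp_", g$amplitude), paste0("freq_", g$frequency),
                    paste0("cum_", g$cumulative), paste0("speed_", g$speed)))
}
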