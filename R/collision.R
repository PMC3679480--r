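#' Resolve merged cores by repeated erosion
#'
#' When two larvae's predicted positions point to the same core, the
#' region of interest around the merged core is eroded repeatedly with a
#' 3x3 element until at least two sufficiently large components emerge.
#'
#' @param roi_mask 0/1 matrix: the region of interest around the merged
#'   core (already restricted to the merged component).
#' @param min_area_px2 Minimum component area (px^2) to count as a core
#'   after splitting (default 4).
#' @param max_iter Erosion cap (default 10).
#' @return A list with `resolved` (logical), `centroids` (k x 2 matrix of
#'   the component centroids, `NULL` if unresolved) and `iterations`.
#' @export
resolve_merged_cores <- function(roi_mask, min_area_px2 = 4, max_iter = 10) {
  m <- roi_mask > 0
  for (it in seq_len(max_iter)) {
    m <- erode3x3(m, 1L)
    if (!any(m > 0)) break
    lab <- label_components(m)
    nmax <- max(lab)
    if (nmax >= 2) {
      areas <- tabulate(lab[lab > 0], nbins = nmax)
      big <- which(areas >= min_area_px2)
      if (length(big) >= 2) {
        cent <- t(vapply(big, function(id) colMeans(component_pixels(lab, id)),
                         numeric(2)))
        o <- order(-areas[big])
        return(list(resolved = TRUE, centroids = cent[o, , drop = FALSE],
                    iterations = it))
      }
    }
  }
  list(resolved = FALSE, centroids = NULL, iterations = max_iter)
}

#' Separate two touching larvae in a merged full-body component
#'
#' A full-body component whose area exceeds the contact threshold and
#' which contains two head centres is split by one of two algorithms,
#' chosen by the core-to-core distance: below the configured distance a
#' cutting line is searched (over orientations and offsets along the
#' inter-core axis) that maximizes the summed area of the two largest
#' resulting components containing one head centre each; above it, the
#' binarization threshold on the underlying grayscale difference image is
#' raised stepwise until the component splits into parts that isolate the
#' two head centres.
#'
#' @param body A `full_body` component (from [extract_full_body()]).
#' @param heads 2 x 2 matrix of the two head-centre positions (x, y).
#' @param diffimg Background-minus-frame difference image (same frame the
#'   binary mask came from); required for the intensity branch.
#' @param cfg A [larva_config()].
#' @param step Intensity-threshold step for the intensity branch.
#' @param n_angles Number of line orientations searched.
#' @return A list with `resolved` (logical), `method` (`"line"`,
#'   `"intensity"` or `"unresolved"`) and `components`: when resolved, a
#'   list of two n x 2 pixel matrices, `components[[k]]` containing
#'   `heads[k, ]` and no other head centre; the two pixel sets are
#'   disjoint.
#' @export
separate_bodies <- function(body, heads, diffimg, cfg = larva_config(),
                            step = 5, n_angles = 36) {
  stopifnot(nrow(heads) == 2)
  mask <- body$labels == body$label
  for (k in 1:2) {
    p <- round(heads[k, ])
    if (!in_mask(mask, p))
      stop("head centre ", k, " is not inside the merged component",
           call. = FALSE)
  }
  d_mm <- pt_dist(heads[1, ], heads[2, ]) * cfg$pixel_size_mm
  if (d_mm < cfg$contact_line_vs_threshold_mm) {
    res <- separate_by_line(mask, heads, n_angles)
    if (res$resolved) { res$method <- "line"; return(res) }
    # fall through to intensity as a backstop
  }
  res <- separate_by_intensity(mask, heads, diffimg, cfg, step)
  if (res$resolved) {
    res$method <- if (d_mm < cfg$contact_line_vs_threshold_mm) "line+intensity"
                  else "intensity"
    return(res)
  }
  list(resolved = FALSE, method = "unresolved", components = NULL)
}

in_mask <- function(mask, p) {
  p[1] >= 1 && p[2] >= 1 && p[1] <= nrow(mask) && p[2] <= ncol(mask) &&
    mask[p[1], p[2]]
}

# component (pixel set) of `labels` containing point p, or NULL
comp_at <- function(labels, p) {
  p <- round(p)
  if (p[1] < 1 || p[2] < 1 || p[1] > nrow(labels) || p[2] > ncol(labels))
    return(NULL)
  id <- labels[p[1], p[2]]
  if (id == 0) {
    # 3x3 fallback
    for (dx in -1:1) for (dy in -1:1) {
      x <- p[1] + dx; y <- p[2] + dy
      if (x >= 1 && y >= 1 && x <= nrow(labels) && y <= ncol(labels) &&
          labels[x, y] > 0) { id <- labels[x, y]; break }
    }
  }
  if (id == 0) return(NULL)
  list(id = id, pixels = component_pixels(labels, id))
}

separate_by_line <- function(mask, heads, n_angles = 36) {
  pts <- which(mask, arr.ind = TRUE)
  mid <- (heads[1, ] + heads[2, ]) / 2
  axis <- heads[2, ] - heads[1, ]
  axis_len <- sqrt(sum(axis^2))
  u <- if (axis_len > 0) axis / axis_len else c(1, 0)
  offsets <- seq(-floor(axis_len / 2) + 1, floor(axis_len / 2) - 1, by = 1)
  if (!length(offsets)) offsets <- 0
  best <- NULL; best_area <- -Inf; best_erased <- Inf
  for (ang in seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]) {
    nvec <- c(cos(ang), sin(ang))  # normal of the cutting line
    for (off in offsets) {
      p0 <- mid + off * u
      # erase pixels within half a pixel of the line through p0 normal nvec
      sd_ <- (pts[, 1] - p0[1]) * nvec[1] + (pts[, 2] - p0[2]) * nvec[2]
      erase <- abs(sd_) <= 0.71
      if (!any(erase) || all(erase)) next
      m2 <- mask
      m2[pts[erase, , drop = FALSE]] <- FALSE
      lab <- label_components(m2)
      c1 <- comp_at(lab, heads[1, ]); c2 <- comp_at(lab, heads[2, ])
      if (is.null(c1) || is.null(c2) || c1$id == c2$id) next
      area <- nrow(c1$pixels) + nrow(c2$pixels)
      erased <- sum(erase)
      if (area > best_area || (area == best_area && erased < best_erased)) {
        best_area <- area; best_erased <- erased
        best <- list(c1$pixels, c2$pixels)
      }
    }
  }
  if (is.null(best)) return(list(resolved = FALSE, components = NULL))
  list(resolved = TRUE, components = best)
}

separate_by_intensity <- function(mask, heads, diffimg, cfg, step = 5) {
  if (is.null(diffimg)) return(list(resolved = FALSE, components = NULL))
  thr <- cfg$binarize_threshold + step
  while (thr <= 250) {
    m2 <- mask & (diffimg > thr)
    if (!any(m2)) break
    lab <- label_components(m2)
    c1 <- comp_at(lab, heads[1, ]); c2 <- comp_at(lab, heads[2, ])
    if (!is.null(c1) && !is.null(c2) && c1$id != c2$id)
      return(list(resolved = TRUE, components = list(c1$pixels, c2$pixels)))
    thr <- thr + step
  }
  list(resolved = FALSE, components = NULL)
}
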