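#' Assign core candidates to larva identities
#'
#' Each larva's position is predicted from its previous two frames
#' (constant-velocity extrapolation) and matched to the closest candidate
#' core, greedily in increasing distance order; ties break toward the
#' lower larva id. A larva left without a candidate keeps its previous
#' state and is flagged invalid for the frame. If two larvae are both
#' closest to the same candidate, or their matched candidates (nearly)
#' coincide, the pair is flagged as a collision for downstream resolution.
#'
#' @param candidates List of candidate cores (as from [segment_cores()]),
#'   or an n x 2 matrix of centroids.
#' @param prev Matrix n_larvae x 2 of positions at frame t-1.
#' @param prev2 Matrix n_larvae x 2 of positions at frame t-2 (or `NULL`;
#'   velocity is then taken as zero).
#' @param merge_dist_px Two matched candidates closer than this are
#'   treated as one merged core (collision).
#' @return A list with `match` (per-larva candidate index or `NA`),
#'   `pred` (predicted positions), `valid` (logical) and `collisions`
#'   (data.frame `a`, `b` of larva-id pairs).
#' @export
assign_identities <- function(candidates, prev, prev2 = NULL,
                              merge_dist_px = 2) {
  cand <- if (is.matrix(candidates)) candidates
          else do.call(rbind, lapply(candidates, `[[`, "centroid"))
  nl <- nrow(prev)
  pred <- prev
  if (!is.null(prev2)) pred <- prev + (prev - prev2)
  match <- rep(NA_integer_, nl)
  nearest <- rep(NA_integer_, nl)
  if (!is.null(cand) && nrow(cand) > 0) {
    d <- matrix(0, nl, nrow(cand))
    for (i in seq_len(nl))
      d[i, ] <- sqrt((cand[, 1] - pred[i, 1])^2 + (cand[, 2] - pred[i, 2])^2)
    for (i in seq_len(nl)) nearest[i] <- which.min(d[i, ])
    dd <- d
    repeat {
      if (all(!is.finite(dd))) break
      k <- arrayInd(which.min(dd), dim(dd))
      i <- k[1]; j <- k[2]
      if (!is.finite(dd[i, j])) break
      match[i] <- j
      dd[i, ] <- Inf
      dd[, j] <- Inf
      if (all(!is.na(match))) break
    }
  }
  valid <- !is.na(match)
  collisions <- data.frame(a = integer(0), b = integer(0))
  if (nl >= 2) {
    for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
      same_nearest <- !is.na(nearest[i]) && !is.na(nearest[j]) &&
        nearest[i] == nearest[j]
      merged <- valid[i] && valid[j] &&
        pt_dist(cand[match[i], ], cand[match[j], ]) < merge_dist_px
      if (same_nearest || merged)
        collisions <- rbind(collisions, data.frame(a = i, b = j))
    }
  }
  list(match = match, pred = pred, valid = valid, collisions = collisions)
}
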