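#' Transition index of maneuver sequences
#'
#' Successions of classified maneuvers in a well are modeled as a Markov
#' chain. For a pair of maneuvers (B1, B2) the transition index is
#' I(B1 -> B2) = p(second = B2 | first = B1) / p(B2), the conditional
#' probability of B2 following B1 divided by the marginal probability of
#' B2. I equals 1 when the order of maneuvers is random, and exceeds 1
#' when B2 preferentially follows B1.
#'
#' Pairs are consecutive movements in the well-wide time ordering. The
#' `variant` restricts which pairs enter the conditional: `"same"` pairs
#' successive movements of the same larva (consecutive within each
#' larva's own sequence), `"different"` takes well-wide consecutive pairs
#' whose two movements belong to different larvae, `"all"` takes every
#' well-wide consecutive pair. The marginal p(B2) is always computed over
#' all movements of the data set.
#'
#' @param movements Data.frame with columns `well`, `larva`, `onset_s`,
#'   `class` (in `{"S","T","E"}`); rows in any order.
#' @param variant `"all"`, `"same"` or `"different"`.
#' @return A `transition_index` list: `I` (3 x 3 matrix, rows = first
#'   maneuver B1, cols = second maneuver B2; `NA` where B1 has no
#'   outgoing pairs), `counts` (3 x 3 pair counts), `marginal`,
#'   `n_pairs`, `variant`.
#' @export
transition_index <- function(movements,
                             variant = c("all", "same", "different")) {
  variant <- match.arg(variant)
  mv <- check_movements(movements)
  cls <- c("S", "T", "E")
  marginal <- prop.table(table(factor(mv$class, levels = cls)))
  pairs <- movement_pairs(mv, variant)
  counts <- matrix(0L, 3, 3, dimnames = list(cls, cls))
  if (nrow(pairs)) {
    tb <- table(factor(pairs$c1, levels = cls), factor(pairs$c2, levels = cls))
    counts <- counts + unclass(tb)
  }
  out <- sum_to_index(counts, as.numeric(marginal))
  structure(list(I = out, counts = counts,
                 marginal = stats::setNames(as.numeric(marginal), cls),
                 n_pairs = nrow(pairs), variant = variant),
            class = "transition_index")
}

sum_to_index <- function(counts, marginal) {
  cls <- rownames(counts)
  I <- matrix(NA_real_, 3, 3, dimnames = dimnames(counts))
  for (r in 1:3) {
    tot <- sum(counts[r, ])
    if (tot > 0) I[r, ] <- (counts[r, ] / tot) / marginal
  }
  I[, marginal == 0] <- NA_real_
  I
}

check_movements <- function(movements) {
  need <- c("well", "larva", "onset_s", "class")
  miss <- setdiff(need, names(movements))
  if (length(miss))
    stop("movements table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(movements$class), c("S", "T", "E"))
  if (length(bad)) stop("unknown maneuver class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  movements[order(movements$well, movements$onset_s), , drop = FALSE]
}

# consecutive pairs per well (and per larva for the same-larva variant)
movement_pairs <- function(mv, variant) {
  out <- NULL
  for (w in unique(mv$well)) {
    m <- mv[mv$well == w, , drop = FALSE]
    if (variant == "same") {
      for (l in unique(m$larva)) {
        s <- m[m$larva == l, , drop = FALSE]
        if (nrow(s) >= 2)
          out <- rbind(out, pair_rows(s, seq_len(nrow(s) - 1),
                                      seq_len(nrow(s) - 1) + 1L))
      }
    } else {
      if (nrow(m) >= 2) {
        i <- seq_len(nrow(m) - 1)
        keep <- if (variant == "different") m$larva[i] != m$larva[i + 1]
                else rep(TRUE, length(i))
        if (any(keep)) out <- rbind(out, pair_rows(m, i[keep], i[keep] + 1L))
      }
    }
  }
  out %||% data.frame(c1 = character(0), c2 = character(0),
                      dt_s = numeric(0), dd_mm = numeric(0))
}

pair_rows <- function(m, i, j) {
  dd <- if (all(c("x_mm", "y_mm") %in% names(m)))
    sqrt((m$x_mm[j] - m$x_mm[i])^2 + (m$y_mm[j] - m$y_mm[i])^2)
  else rep(NA_real_, length(i))
  data.frame(c1 = m$class[i], c2 = m$class[j],
             dt_s = m$onset_s[j] - m$onset_s[i], dd_mm = dd,
             stringsAsFactors = FALSE)
}

# all ordered pairs within the maximal time window, per well, optionally
# restricted to same- or different-larva pairs; successor_only keeps, for
# each second movement, only its most recent in-window predecessor. The
# pairing depends only on identities, times and positions, never on the
# class labels, so it can be computed once and reused across label
# permutations. Returns row indices into `mv` plus dt and dd.
windowed_pairs <- function(mv, variant, max_dt_s, successor_only = FALSE) {
  acc <- vector("list", nrow(mv)); na <- 0L
  for (w in unique(mv$well)) {
    rows <- which(mv$well == w)
    n <- length(rows)
    if (n < 2) next
    t_on <- mv$onset_s[rows]
    lar <- mv$larva[rows]
    for (j in 2:n) {
      i <- j - 1
      pick <- integer(0)
      while (i >= 1 && t_on[j] - t_on[i] <= max_dt_s) {
        okv <- switch(variant,
                      all = TRUE,
                      same = lar[i] == lar[j],
                      different = lar[i] != lar[j])
        if (okv) {
          pick <- c(pick, i)
          if (successor_only) break
        }
        i <- i - 1
      }
      if (length(pick)) {
        na <- na + 1L
        acc[[na]] <- cbind(rows[pick], rows[j])
      }
    }
  }
  m <- if (na) do.call(rbind, acc[seq_len(na)]) else
    matrix(integer(0), 0, 2)
  ii <- m[, 1]; jj <- m[, 2]
  dd <- sqrt((mv$x_mm[jj] - mv$x_mm[ii])^2 + (mv$y_mm[jj] - mv$y_mm[ii])^2)
  data.frame(i = ii, j = jj, dt_s = mv$onset_s[jj] - mv$onset_s[ii],
             dd_mm = dd)
}

# per-cell transition index from precomputed pairs and class labels
grid_from_pairs <- function(classes, pairs, time_edges, dist_edges,
                            marginal, min_count) {
  cls <- c("S", "T", "E")
  tf <- cut(pairs$dt_s, time_edges, right = FALSE, include.lowest = TRUE)
  df <- cut(pairs$dd_mm, dist_edges, right = FALSE, include.lowest = TRUE)
  c1 <- factor(classes[pairs$i], levels = cls)
  c2 <- factor(classes[pairs$j], levels = cls)
  tab <- table(tf, df, c1, c2)
  nt <- length(time_edges) - 1; nd <- length(dist_edges) - 1
  grid <- NULL
  I_max <- matrix(NA_real_, 3, 3, dimnames = list(cls, cls))
  for (ti in seq_len(nt)) for (di in seq_len(nd)) {
    counts <- tab[ti, di, , ]
    for (r in 1:3) {
      tot <- sum(counts[r, ])
      for (cc in 1:3) {
        I <- if (tot >= min_count && marginal[cc] > 0)
          (counts[r, cc] / tot) / marginal[cc] else NA_real_
        grid <- rbind(grid, data.frame(
          pair = paste0(cls[r], "-", cls[cc]), b1 = cls[r], b2 = cls[cc],
          t_lo = time_edges[ti], t_hi = time_edges[ti + 1],
          d_lo = dist_edges[di], d_hi = dist_edges[di + 1],
          n_pairs = as.integer(counts[r, cc]), I = I,
          stringsAsFactors = FALSE))
        if (!is.na(I) && (is.na(I_max[r, cc]) || I > I_max[r, cc]))
          I_max[r, cc] <- I
      }
    }
  }
  list(grid = grid, I_max = I_max)
}

#' Transition index over time and distance windows
#'
#' Movement pairs are binned by the interval between the onsets of the
#' two movements and by the distance between the two larvae's core
#' positions at onset. The index I is computed per cell with the
#' cell-restricted conditional probability and the partition-wide
#' marginal; cells with fewer outgoing pairs than `min_count` are masked.
#'
#' @param movements Data.frame as in [transition_index()], with
#'   additional onset-position columns `x_mm`, `y_mm`.
#' @param time_edges Increasing vector of time-bin edges (s).
#' @param dist_edges Increasing vector of distance-bin edges (mm).
#' @param variant `"same"`, `"different"` or `"all"`.
#' @param min_count Minimum outgoing-pair count per cell (default 20).
#' @param successor_only If `TRUE`, each movement is paired only with its
#'   most recent in-window predecessor instead of all ordered pairs.
#' @return A `transition_grid` list: `grid` (long data.frame: `pair`,
#'   `b1`, `b2`, `t_lo`, `t_hi`, `d_lo`, `d_hi`, `n_pairs`, `I`),
#'   `I_max` (3 x 3 matrix of per-pair maxima over cells), `marginal`,
#'   `variant`.
#' @export
windowed_index <- function(movements, time_edges, dist_edges,
                           variant = c("same", "different", "all"),
                           min_count = 20, successor_only = FALSE) {
  variant <- match.arg(variant)
  if (length(time_edges) < 2 || length(dist_edges) < 2)
    stop("time_edges and dist_edges each need at least two values",
         call. = FALSE)
  mv <- check_movements(movements)
  if (!all(c("x_mm", "y_mm") %in% names(mv)))
    stop("windowed_index needs onset positions (columns x_mm, y_mm)",
         call. = FALSE)
  cls <- c("S", "T", "E")
  marginal <- as.numeric(prop.table(table(factor(mv$class, levels = cls))))
  pairs <- windowed_pairs(mv, variant, max(time_edges), successor_only)
  g <- grid_from_pairs(mv$class, pairs, time_edges, dist_edges, marginal,
                       min_count)
  structure(list(grid = g$grid, I_max = g$I_max,
                 marginal = stats::setNames(marginal, cls),
                 variant = variant, min_count = min_count,
                 successor_only = successor_only),
            class = "transition_grid")
}

#' Permutation test for the maximal transition index
#'
#' Tests whether the observed maximal transition index of a maneuver pair
#' over the time x distance grid exceeds what label order alone would
#' produce: maneuver labels are randomly permuted across movements while
#' larva identities, times and locations stay fixed, and I_max is
#' recomputed for each permutation. The observed value is compared to the
#' permutation sample with a one-sample t-test (the test the procedure
#' prescribes), complemented by an exceedance permutation p-value
#' (1 + #{null >= observed}) / (n + 1).
#'
#' @param movements Data.frame as for [windowed_index()].
#' @param pair Character vector `c(B1, B2)`.
#' @param time_edges,dist_edges,variant,min_count,successor_only Passed
#'   to [windowed_index()].
#' @param n_perm Number of permutations (default 50).
#' @param seed Integer seed.
#' @return A list: `observed` I_max, `null` (permutation sample),
#'   `null_mean`, `null_sd`, `p_t` (t-test), `p_perm` (exceedance),
#'   `degenerate` (zero-variance null).
#' @export
permutation_test <- function(movements, pair, time_edges, dist_edges,
                             variant = c("same", "different", "all"),
                             n_perm = 50, seed = 1, min_count = 20,
                             successor_only = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(pair) == 2, all(pair %in% c("S", "T", "E")))
  mv <- check_movements(movements)
  if (nrow(mv) < 2) stop("need at least 2 movements", call. = FALSE)
  cls <- c("S", "T", "E")
  marginal <- as.numeric(prop.table(table(factor(mv$class, levels = cls))))
  pairs <- windowed_pairs(mv, variant, max(time_edges), successor_only)
  i_max_of <- function(classes)
    grid_from_pairs(classes, pairs, time_edges, dist_edges, marginal,
                    min_count)$I_max[pair[1], pair[2]]
  obs <- i_max_of(mv$class)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) i_max_of(sample(mv$class)), 0)
  })
  null_ok <- null[!is.na(null)]
  degen <- length(null_ok) < 2 || stats::sd(null_ok) == 0
  p_t <- if (is.na(obs)) NA_real_
         else if (degen) as.numeric(obs <= mean(null_ok))
         else stats::t.test(null_ok, mu = obs,
                            alternative = "less")$p.value
  p_perm <- if (is.na(obs)) NA_real_
            else (1 + sum(null_ok >= obs)) / (length(null_ok) + 1)
  list(observed = obs, null = null, null_mean = mean(null_ok),
       null_sd = stats::sd(null_ok), p_t = p_t, p_perm = p_perm,
       degenerate = degen)
}

#' Simulate a table of classified movements in wells
#'
#' Generates maneuver sequences that emulate groups of larvae swimming in
#' beat-and-glide style: each larva produces movements as a renewal
#' process, labels are drawn i.i.d. from the given marginals, and onset
#' positions are uniform in the well. Optionally a pairwise enrichment is
#' planted: when the most recent movement (of another larva for variant
#' `"different"`, the same larva for `"same"`) within the given time and
#' distance window has class `enrich$pair[1]`, the new movement takes
#' class `enrich$pair[2]` with probability `factor` times its marginal.
#'
#' @param n_movements Approximate total number of movements.
#' @param n_larvae Larvae per well.
#' @param n_wells Number of wells.
#' @param marginals Named probabilities for S, T, E.
#' @param rate_hz Per-larva movement rate (default 0.45, i.e. one
#'   movement every 2.2 s).
#' @param well_radius_mm Well radius (default 11, a 2.2 cm dish).
#' @param enrich `NULL` or a list with `pair` (e.g. `c("E","E")`),
#'   `time_s`, `dist_mm`, `factor`, `variant`.
#' @param seed Integer seed.
#' @return Movements data.frame: `well`, `larva`, `onset_s`, `x_mm`,
#'   `y_mm`, `class`.
#' @export
simulate_maneuver_sequence <- function(n_movements, n_larvae = 7,
                                       n_wells = 1,
                                       marginals = c(S = 0.35, T = 0.48, E = 0.16),
                                       rate_hz = 0.45, well_radius_mm = 11,
                                       enrich = NULL, seed = 1) {
  if (abs(sum(marginals) - 1) > 0.05)
    stop("marginals must sum to (approximately) 1", call. = FALSE)
  cls <- c("S", "T", "E")
  p <- as.numeric(marginals[cls])
  p <- p / sum(p)  # printed probabilities may round to a sum slightly off 1
  per_larva <- ceiling(n_movements / (n_larvae * n_wells))
  with_seed(seed, {
    out <- NULL
    for (w in seq_len(n_wells)) {
      t_on <- lapply(seq_len(n_larvae), function(l)
        cumsum(stats::rexp(per_larva, rate_hz)))
      m <- data.frame(
        well = w,
        larva = rep(seq_len(n_larvae), each = per_larva),
        onset_s = unlist(t_on))
      rr <- well_radius_mm * sqrt(stats::runif(nrow(m)))
      th <- stats::runif(nrow(m), 0, 2 * pi)
      m$x_mm <- rr * cos(th); m$y_mm <- rr * sin(th)
      m <- m[order(m$onset_s), , drop = FALSE]
      if (is.null(enrich)) {
        m$class <- sample(cls, nrow(m), TRUE, prob = p)
      } else {
        # two passes: the enriched conditional is factor x the realized
        # marginal, so the planted index comes out at `factor` despite the
        # enrichment itself inflating the marginal
        k2 <- match(enrich$pair[2], cls)
        q <- enrich$factor * p[k2]
        for (pass in 1:3) {   # iterate the q = factor * marginal fixed point
          m$class <- assign_enriched_labels(m, cls, p, q, enrich)
          q <- enrich$factor * mean(m$class == cls[k2])
        }
      }
      out <- rbind(out, m)
    }
    rownames(out) <- NULL
    out
  })
}

assign_enriched_labels <- function(m, cls, p, q, enrich) {
  k2 <- match(enrich$pair[2], cls)
  labels <- rep(NA_character_, nrow(m))
  p2 <- p
  p2[k2] <- min(1, q)
  rest <- setdiff(seq_along(cls), k2)
  p2[rest] <- p[rest] * (1 - p2[k2]) / sum(p[rest])
  for (i in seq_len(nrow(m))) {
    # most recent predecessor of the right variant in the time window
    prev <- NA_integer_
    j <- i - 1
    while (j >= 1 && m$onset_s[i] - m$onset_s[j] <= enrich$time_s) {
      okv <- switch(enrich$variant %||% "different",
                    different = m$larva[j] != m$larva[i],
                    same = m$larva[j] == m$larva[i],
                    all = TRUE)
      if (okv) { prev <- j; break }
      j <- j - 1
    }
    in_window <- !is.na(prev) &&
      sqrt((m$x_mm[i] - m$x_mm[prev])^2 +
           (m$y_mm[i] - m$y_mm[prev])^2) <= enrich$dist_mm
    labels[i] <- if (in_window && labels[prev] == enrich$pair[1])
      sample(cls, 1, prob = p2)
    else
      sample(cls, 1, prob = p)
  }
  labels
}

#' @export
print.transition_index <- function(x, ...) {
  cat(sprintf("<transition_index> variant = %s, %d pairs\n", x$variant,
              x$n_pairs))
  print(round(x$I, 3))
  invisible(x)
}

#' @export
print.transition_grid <- function(x, ...) {
  cat(sprintf("<transition_grid> variant = %s; I_max:\n", x$variant))
  print(round(x$I_max, 3))
  invisible(x)
}
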