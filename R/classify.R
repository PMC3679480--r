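#' Fit the two-stage maneuver classifier
#'
#' The 53 raw feature components are z-scored, reduced by PCA to the
#' first 14 principal components, and the z-scored total bout duration is
#' appended, giving a 15-dimensional representation. Two linear
#' support-vector machines are trained in cascade: stage 1 separates slow
#' forward swims (S) from the rest; stage 2, trained on the non-S
#' examples only, separates routine turns (T) from escapes (E). The
#' linear separators are stored as explicit weight vectors, so the model
#' serializes to plain JSON.
#'
#' @param X n x 53 raw feature matrix (rows from [extract_features()]).
#' @param duration_ms Length-n vector of bout durations.
#' @param labels Character vector in `{"S", "T", "E"}`.
#' @param cfg A [larva_config()].
#' @param cost SVM regularization parameter (linear kernel; default 1).
#' @param n_components Number of principal components kept (default 14).
#' @param seed Integer seed (the fit itself is deterministic; the seed
#'   fixes any library-internal randomness).
#' @return A `maneuver_classifier` list: standardization vectors, PCA
#'   `rotation` (53 x 14) and `explained_variance` of the kept
#'   components, stage weight vectors `w1`/`rho1` (S vs rest) and
#'   `w2`/`rho2` (T vs E), and training metadata.
#' @export
fit_model <- function(X, duration_ms, labels, cfg = larva_config(),
                      cost = 1, n_components = 14, seed = 1) {
  stopifnot(nrow(X) == length(labels), ncol(X) == 53,
            length(duration_ms) == nrow(X))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("S", "T", "E"))
  if (length(bad)) stop("unknown class label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(labels, levels = c("S", "T", "E")))
  if (any(counts < 5))
    stop("each class needs at least 5 training examples (got ",
         paste(counts, collapse = "/"), " for S/T/E)", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  expl <- sum(pca$sdev[seq_len(k)]^2) / sum(pca$sdev^2)
  dctr <- mean(duration_ms)
  dscl <- stats::sd(duration_ms)
  if (is.na(dscl) || dscl == 0) dscl <- 1
  feat <- cbind(Z %*% rot, (duration_ms - dctr) / dscl)

  with_seed(seed, {
    s1 <- linear_svm(feat, factor(ifelse(labels == "S", "S", "O"),
                                  levels = c("S", "O")), cost)
    te <- labels != "S"
    s2 <- linear_svm(feat[te, , drop = FALSE],
                     factor(labels[te], levels = c("T", "E")), cost)
  })

  structure(list(center = ctr, scale = scl, rotation = rot,
                 explained_variance = expl,
                 duration_center = dctr, duration_scale = dscl,
                 w1 = s1$w, rho1 = s1$rho, w2 = s2$w, rho2 = s2$rho,
                 cost = cost, n = nrow(X),
                 class_counts = as.integer(counts)),
            class = "maneuver_classifier")
}

# linear SVM reduced to an explicit separator: decision value
# x %*% w - rho, positive for the first factor level
linear_svm <- function(x, y, cost) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  pr <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  dv <- drop(x %*% w) - rho
  # align the explicit separator with predict()'s decision values, then
  # orient so that positive means the first factor level
  if (sum((dv - pr[, 1])^2) > sum((dv + pr[, 1])^2)) { w <- -w; rho <- -rho }
  if (sub("/.*", "", colnames(pr)[1]) != levels(y)[1]) { w <- -w; rho <- -rho }
  list(w = w, rho = rho)
}

#' Classify movements with a fitted maneuver classifier
#'
#' Stage 1 decides S vs not-S; when not-S (including exactly on the
#' boundary), stage 2 decides T vs E.
#'
#' @param model A `maneuver_classifier` from [fit_model()].
#' @param X n x 53 raw feature matrix (or a single `movement_features`).
#' @param duration_ms Bout durations (taken from the features object if
#'   one is given).
#' @return Character vector of labels in `{"S", "T", "E"}`.
#' @export
classify <- function(model, X, duration_ms = NULL) {
  stopifnot(inherits(model, "maneuver_classifier"))
  if (inherits(X, "movement_features")) {
    duration_ms <- X$duration_ms
    X <- matrix(X$raw, 1)
  }
  if (is.null(dim(X))) X <- matrix(X, 1)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  feat <- cbind(Z %*% model$rotation,
                (duration_ms - model$duration_center) / model$duration_scale)
  dv1 <- drop(feat %*% model$w1) - model$rho1
  dv2 <- drop(feat %*% model$w2) - model$rho2
  ifelse(dv1 > 0, "S", ifelse(dv2 > 0, "T", "E"))
}

#' Save / load a maneuver classifier as JSON
#'
#' @param model A `maneuver_classifier`.
#' @param path File path.
#' @return `load_model()` returns the `maneuver_classifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "maneuver_classifier"))
  obj <- unclass(model)
  obj$rotation <- as.data.frame(obj$rotation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rotation <- as.matrix(obj$rotation)
  obj$center <- as.numeric(obj$center)
  obj$scale <- as.numeric(obj$scale)
  obj$w1 <- as.numeric(obj$w1); obj$w2 <- as.numeric(obj$w2)
  structure(obj, class = "maneuver_classifier")
}

#' @export
print.maneuver_classifier <- function(x, ...) {
  cat(sprintf("<maneuver_classifier> trained on %d movements (S/T/E = %s); %d PCs explain %.1f%% variance\n",
              x$n, paste(x$class_counts, collapse = "/"),
              ncol(x$rotation), 100 * x$explained_variance))
  invisible(x)
}

#' Generate a synthetic archetype training set
#'
#' Simulates labeled single-maneuver bend traces and core tracks from the
#' three maneuver archetypes, with per-movement variability in amplitude,
#' frequency, duration and speed, runs movement detection, and extracts
#' the feature vectors — a fully synthetic stand-in for a manually
#' labeled training set.
#'
#' @param n Number of movements to draw.
#' @param cfg A [larva_config()].
#' @param seed Integer seed.
#' @param class_probs Sampling probabilities for S, T, E (defaults to the
#'   wild-type class frequencies 0.35/0.48/0.16, renormalized).
#' @param noise_sd_deg Trace noise (deg).
#' @param jitter Relative archetype parameter variability (default 0.2:
#'   parameters scaled by Uniform(1 - jitter, 1 + jitter)).
#' @return A list: `X` (n x 53 feature matrix), `duration_ms`, `labels`.
#'   Movements whose detection or feature extraction fails are dropped.
#' @export
synthetic_training_set <- function(n, cfg = larva_config(), seed = 1,
                                   class_probs = c(S = 0.35, T = 0.48, E = 0.16),
                                   noise_sd_deg = 0.5, jitter = 0.2) {
  p <- as.numeric(class_probs) / sum(class_probs)
  with_seed(seed, {
    X <- matrix(NA_real_, n, 53)
    dur <- rep(NA_real_, n)
    lab <- rep(NA_character_, n)
    for (k in seq_len(n)) {
      cl <- sample(c("S", "T", "E"), 1, prob = p)
      arch <- maneuver_archetype(cl)
      for (f in c("amplitude_deg", "freq_hz", "duration_ms",
                  "peak_speed_mm_s"))
        arch[[f]] <- arch[[f]] * stats::runif(1, 1 - jitter, 1 + jitter)
      tb <- synth_bend_trace(list(list(start_ms = 50, archetype = arch)),
                             arch$duration_ms + 150,
                             noise_sd_deg = noise_sd_deg,
                             seed = sample.int(2^31 - 1, 1), cfg = cfg)
      trc <- clean_trace(tb$angle_deg, cfg = cfg)
      t_ms <- (seq_along(trc) - 1) * 1000 / cfg$frame_rate_hz
      spd <- archetype_speed(arch, t_ms - 50)
      track <- cbind(100 + cumsum(spd / cfg$frame_rate_hz / cfg$pixel_size_mm),
                     100)
      ev <- detect_movements(trc, track = track, cfg = cfg)
      if (nrow(ev) != 1) next
      fv <- tryCatch(extract_features(ev[1, ], trc, track, cfg),
                     error = function(e) NULL)
      if (is.null(fv)) next
      X[k, ] <- fv$raw; dur[k] <- fv$duration_ms; lab[k] <- cl
    }
    ok <- !is.na(lab)
    list(X = X[ok, , drop = FALSE], duration_ms = dur[ok], labels = lab[ok])
  })
}
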