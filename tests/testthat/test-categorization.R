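test_that("the raw feature vector has the documented 53-bin structure", {
  g <- larvatrack:::.feature_grid
  expect_length(g$amplitude, 15)
  expect_length(g$frequency, 14)
  expect_length(g$cumulative, 14)
  expect_length(g$speed, 10)
  expect_equal(sum(lengths(g)), 53)
  expect_true(all(diff(g$amplitude) == 12))
  expect_true(all(diff(g$frequency) == 7))
  expect_true(all(diff(g$speed) == 24))
  expect_lte(max(g$amplitude), 178)
  expect_lte(max(g$frequency), 104)
  expect_lte(max(g$speed), 240)
})

test_that("features of a pure sinusoid match closed forms", {
  cfg <- fx_cfg()
  fps <- cfg$frame_rate_hz
  n <- round(0.35 * fps)
  t_s <- (0:(n - 1)) / fps
  a <- 20 * sin(2 * pi * 25 * t_s)
  ev <- data.frame(start_frame = 1, end_frame = n)
  fv <- extract_features(ev, a, track = NULL, cfg = cfg)
  expect_length(fv$raw, 53)
  g <- larvatrack:::.feature_grid
  freq <- fv$raw[paste0("freq_", g$frequency)]
  # extrema timings are frame-quantized: a 25 Hz alternation sampled at
  # 337 Hz yields half-periods of 6 or 7 frames, i.e. 24.07-28.08 Hz
  expect_true(all(freq >= fps / 14 - 1e-9 & freq <= fps / 12 + 1e-9))
  # amplitude samples trace |20 sin| from the first peak: near 20 at the
  # extremum bins, small near the zero crossings, strongly correlated
  amp <- fv$raw[paste0("amp_", g$amplitude)]
  expected <- abs(20 * cos(2 * pi * 25 * g$amplitude / 1000))
  peak_bins <- g$amplitude %% 60 == 0   # multiples of 1.5 periods
  expect_true(all(amp[peak_bins] > 17))
  expect_gt(stats::cor(amp, expected), 0.8)
  # stationary core: all speed bins zero
  expect_true(all(fv$raw[paste0("speed_", g$speed)] == 0))
})

test_that("short events are padded and flagged, flat ones error", {
  cfg <- fx_cfg()
  fps <- cfg$frame_rate_hz
  n <- round(0.08 * fps)
  a <- 15 * sin(2 * pi * 25 * (0:(n - 1)) / fps)
  fv <- extract_features(data.frame(start_frame = 1, end_frame = n), a,
                         NULL, cfg)
  expect_true(fv$padded)
  expect_false(anyNA(fv$raw))
  expect_error(
    extract_features(data.frame(start_frame = 1, end_frame = 50),
                     rep(0, 50), NULL, cfg),
    "no bend extremum")
})

test_that("the two-stage classifier separates the archetypes", {
  cfg <- fx_cfg()
  tr <- synthetic_training_set(300, cfg, seed = 101)
  te <- synthetic_training_set(150, cfg, seed = 909)
  expect_true(all(table(tr$labels) >= 5))

  m <- fit_model(tr$X, tr$duration_ms, tr$labels, cfg, seed = 5)
  expect_equal(dim(m$rotation), c(53, 14))
  expect_gte(m$explained_variance, 0.8)

  # linearly separable training set: perfect training accuracy
  expect_equal(mean(classify(m, tr$X, tr$duration_ms) == tr$labels), 1)

  # held-out accuracy
  pred <- classify(m, te$X, te$duration_ms)
  expect_gte(mean(pred == te$labels), 0.9)
  for (cl in c("S", "T", "E"))
    expect_gte(mean(pred[te$labels == cl] == cl), 0.9)

  # planted class proportions recovered within 3 points
  prop_pred <- table(factor(pred, c("S", "T", "E"))) / length(pred)
  prop_true <- table(factor(te$labels, c("S", "T", "E"))) / length(te$labels)
  expect_true(all(abs(prop_pred - prop_true) < 0.03 + 1e-9))
})

test_that("refitting with the same seed reproduces the separators", {
  cfg <- fx_cfg()
  tr <- synthetic_training_set(120, cfg, seed = 33)
  m1 <- fit_model(tr$X, tr$duration_ms, tr$labels, cfg, seed = 2)
  m2 <- fit_model(tr$X, tr$duration_ms, tr$labels, cfg, seed = 2)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(m1$rotation, m2$rotation)
})

test_that("a model survives a JSON round trip", {
  cfg <- fx_cfg()
  tr <- synthetic_training_set(120, cfg, seed = 33)
  te <- synthetic_training_set(60, cfg, seed = 44)
  m <- fit_model(tr$X, tr$duration_ms, tr$labels, cfg)
  p <- withr::local_tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(classify(m2, te$X, te$duration_ms),
               classify(m, te$X, te$duration_ms))
})

test_that("classification is invariant to left/right mirroring", {
  cfg <- fx_cfg()
  tr <- synthetic_training_set(150, cfg, seed = 33)
  m <- fit_model(tr$X, tr$duration_ms, tr$labels, cfg)
  # mirroring negates the bend trace; features use |angle|, so the
  # feature vector and hence the class are unchanged
  arch <- maneuver_archetype("T")
  tb <- synth_bend_trace(list(list(start_ms = 50, archetype = arch)), 420,
                         0, seed = 1, cfg = cfg, first_bend_sign = 1)
  trc <- clean_trace(tb$angle_deg, cfg = cfg)
  ev <- detect_movements(trc, cfg = cfg)
  f1 <- extract_features(ev[1, ], trc, NULL, cfg)
  f2 <- extract_features(ev[1, ], -trc, NULL, cfg)
  expect_equal(f1$raw, f2$raw, tolerance = 1e-12)
  expect_equal(classify(m, f1), classify(m, f2))
})

test_that("training requires all three classes", {
  cfg <- fx_cfg()
  tr <- synthetic_training_set(80, cfg, seed = 33)
  keep <- tr$labels != "E"
  expect_error(fit_model(tr$X[keep, ], tr$duration_ms[keep],
                         tr$labels[keep], cfg),
               "at least 5")
})
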