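test_that("empty schedule gives an all-zero trace with no events", {
  tb <- synth_bend_trace(data.frame(start_ms = numeric(0),
                                    class = character(0)),
                         duration_ms = 500, noise_sd_deg = 0, seed = 1)
  expect_true(all(tb$angle_deg == 0))
  expect_equal(nrow(tb$events), 0)
})

test_that("a scheduled maneuver oscillates at its archetype frequency", {
  cfg <- larva_config()
  arch <- maneuver_archetype("S", freq_hz = 25, duration_ms = 200)
  tb <- synth_bend_trace(list(list(start_ms = 100, archetype = arch)),
                         500, noise_sd_deg = 0, seed = 2, cfg = cfg)
  ev <- tb$events
  seg <- tb$angle_deg[ev$start_frame:ev$end_frame]
  # dominant discrete Fourier frequency of the event segment
  sp <- Mod(stats::fft(seg - mean(seg)))[2:(length(seg) %/% 2)]
  f_peak <- (which.max(sp)) * cfg$frame_rate_hz / length(seg)
  expect_lt(abs(f_peak - 25), 2)
})

test_that("event bookkeeping is exact and overlap is rejected", {
  sched <- data.frame(start_ms = c(100, 500), class = c("S", "E"))
  tb <- synth_bend_trace(sched, 1000, noise_sd_deg = 0.1, seed = 3)
  expect_equal(nrow(tb$events), 2)
  expect_equal(tb$events$class, c("S", "E"))
  expect_true(all(tb$events$start_frame < tb$events$end_frame))
  expect_true(all(diff(tb$events$start_frame) > 0))

  expect_error(
    synth_bend_trace(data.frame(start_ms = c(100, 150),
                                class = c("S", "S")), 1000, 0, 1),
    "overlap")
  expect_error(
    synth_bend_trace(data.frame(start_ms = 900, class = "S"), 1000, 0, 1),
    "beyond")
})

test_that("trace generation is deterministic given the seed", {
  sched <- data.frame(start_ms = c(100, 500), class = c("T", "E"))
  a <- synth_bend_trace(sched, 1000, noise_sd_deg = 0.5, seed = 9)
  b <- synth_bend_trace(sched, 1000, noise_sd_deg = 0.5, seed = 9)
  expect_identical(a$angle_deg, b$angle_deg)
})

test_that("a resting larva renders identically in every frame", {
  lay <- well_layout(1, radius_px = 80)
  sc <- larva_script(1, x = lay$wells$cx, y = lay$wells$cy)
  vid <- render_video(lay, list(sc), n_frames = 5, seed = 1, noise_sd = 0)
  for (i in 2:5) expect_identical(vid$frames[[i]], vid$frames[[1]])
  expect_true(all(vid$truth$bend_deg == 0))
})

test_that("rendering is bit-identical under the same seed", {
  lay <- well_layout(1, radius_px = 80)
  sc <- larva_script(1, x = lay$wells$cx - 10, y = lay$wells$cy,
                     events = data.frame(start_ms = 30, class = "E"))
  a <- render_video(lay, list(sc), 60, seed = 11, noise_sd = 2)
  b <- render_video(lay, list(sc), 60, seed = 11, noise_sd = 2)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth$bend_deg, b$truth$bend_deg)
})

test_that("the rendered head blob centroid matches the ground-truth core", {
  f <- fx_single_larva()
  vid <- f$video
  cfg <- fx_cfg()
  for (i in c(1, 60, 120, 180)) {
    # intensity-weighted centroid of dark pixels near the true core
    d <- f$background - vid$frames[[i]]
    gc <- vid$truth$core[i, , 1]
    xs <- round(gc[1]) + (-8:8); ys <- round(gc[2]) + (-8:8)
    w <- pmax(d[xs, ys], 0)
    w[w < 40] <- 0          # head pixels only (tail is lighter)
    cx <- sum(outer(xs, rep(1, 17)) * w) / sum(w)
    cy <- sum(outer(rep(1, 17), ys) * w) / sum(w)
    expect_lt(sqrt(sum((c(cx, cy) - gc)^2)), 1)
  }
})

test_that("crossing larvae produce a merged over-threshold component", {
  cfg <- fx_cfg()
  lay <- well_layout(1, radius_px = 110)
  scs <- fx_cross_scripts(lay, 90, 14, 41)
  vid <- render_video(lay, scs, 41, cfg, seed = 2, noise_sd = 0)
  bg <- fx_background(lay)
  mid <- 21   # both larvae at the well centre
  seg <- segment_cores(vid$frames[[mid]], bg, cfg)
  lab <- larvatrack:::label_components(seg$binary)
  a1 <- lab[round(vid$truth$core[mid, 1, 1]), round(vid$truth$core[mid, 2, 1])]
  a2 <- lab[round(vid$truth$core[mid, 1, 2]), round(vid$truth$core[mid, 2, 2])]
  expect_equal(a1, a2)   # one connected component holds both larvae
  expect_gt(sum(lab == a1), cfg$contact_area_px2)
  # ground truth keeps both identities
  expect_false(anyNA(vid$truth$core[, , 1:2]))
})

test_that("a larva placed outside its well is rejected", {
  lay <- well_layout(1, radius_px = 60)
  sc <- larva_script(1, x = lay$wells$cx + 70, y = lay$wells$cy)
  expect_error(render_video(lay, list(sc), 2, seed = 1), "outside")
})

test_that("ground-truth midline length stays within the tail bounds", {
  f <- fx_single_larva()
  cfg <- fx_cfg()
  lens <- apply(f$video$truth$midline[, , , 1], 3, function(m)
    sum(sqrt(rowSums(diff(m)^2))) * cfg$pixel_size_mm)
  expect_true(all(lens > cfg$tail_length_min_mm))
  expect_true(all(lens < cfg$tail_length_max_mm))
})
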