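# helper: build a synthetic binary body (ellipse head + rectangular tail)
# directly as a mask, for cases the renderer does not produce
mask_body <- function(w = 200, h = 200, head = c(60, 100), a = 6, b = 4.5,
                      tail_len = 40, tail_hw = 2) {
  m <- matrix(0L, w, h)
  for (x in 1:w) for (y in 1:h) {
    if (((x - head[1]) / a)^2 + ((y - head[2]) / b)^2 <= 1) m[x, y] <- 1L
  }
  xs <- (head[1] - a - tail_len):(head[1] - a + 2)
  ys <- (head[2] - tail_hw):(head[2] + tail_hw)
  m[xs, ys] <- 1L
  m
}

test_that("full-body extraction finds the component under the core", {
  fs <- fx_single_frame()
  body <- extract_full_body(fs$seg$binary, fs$seg$cores[[1]]$centroid)
  # area close to the rendered head + tail footprint
  expect_gt(body$area, 150)
  expect_lt(body$area, fx_cfg()$contact_area_px2)

  # centroid on background with a foreground neighbour falls back
  m <- matrix(0L, 20, 20); m[10:15, 10:15] <- 1L
  b2 <- extract_full_body(m, c(9, 10))
  expect_equal(b2$area, 36)

  expect_error(extract_full_body(matrix(0L, 20, 20), c(10, 10)),
               "body-missing")
})

test_that("the tail tip lands on the caudal extreme of a straight larva", {
  fs <- fx_single_frame()
  vid <- fs$video
  core <- fs$seg$cores[[1]]$centroid
  body <- extract_full_body(fs$seg$binary, core)
  tp <- find_tail_tip(body, core, vid$truth$heading[1, 1], fx_cfg())
  gt_tip <- vid$truth$tip[1, , 1] - c(fs$x_off, fs$y_off)
  expect_lt(sqrt(sum((tp - gt_tip)^2)), 2)
})

test_that("tip selection on a bent larva stays accurate", {
  cfg <- fx_cfg()
  lay <- well_layout(1, radius_px = 120)
  sc <- larva_script(1, x = lay$wells$cx, y = lay$wells$cy, heading_deg = 25,
                     events = data.frame(start_ms = 5, class = "E",
                                         turn_sign = 1))
  vid <- render_video(lay, list(sc), 30, cfg, seed = 4, noise_sd = 0)
  bg <- fx_background(lay)
  # frame near the first bend peak: strongly C-bent body
  i <- which.max(abs(vid$truth$bend_deg[, 1]))
  seg <- segment_cores(vid$frames[[i]], bg, cfg)
  core <- seg$cores[[1]]$centroid
  body <- extract_full_body(seg$binary, core)
  tp <- find_tail_tip(body, core, vid$truth$heading[i, 1], cfg)
  expect_lt(sqrt(sum((tp - vid$truth$tip[i, , 1])^2)), 3)
})

test_that("asymmetric contour-arc candidates are excluded by the ratio rule", {
  # d1 = 100, d2 = 180 steps: ratio 80/280 > 0.25
  d <- c(100, 180)
  ratio <- abs(d[1] - d[2]) / (d[1] + d[2])
  expect_gt(ratio, 0.25)
  # and the arc-distance computation reproduces such distances on a
  # closed contour where the path to A2 must not pass A1
  dd <- larvatrack:::contour_arc_dists(n = 300, i = 120, iA1 = 20, iA2 = 300)
  expect_equal(dd[1], 100)
  expect_equal(dd[2], 180)
})

test_that("the midline of a symmetric straight body lies on its axis", {
  cfg <- fx_cfg()
  lay <- well_layout(1, radius_px = 100)
  cy <- lay$wells$cy
  sc <- larva_script(1, x = lay$wells$cx, y = cy, heading_deg = 0)
  vid <- render_video(lay, list(sc), 2, cfg, seed = 1, noise_sd = 0)
  tr <- track_well(vid, NULL, cfg, background = fx_background(lay))
  ml <- tr$midline[, , 1, 1]
  expect_true(all(abs(ml[, 2] - cy) < 0.5))
  # points strictly ordered in arc length
  expect_true(all(diff(larvatrack:::cum_arc(ml)) > 0))

  # the synthetic flat-ended mask still yields a valid ordered midline
  m <- mask_body()
  body <- extract_full_body(m, c(60, 100))
  tp <- find_tail_tip(body, c(60, 100), 0, cfg)
  ml2 <- compute_midline(tp, c(60 - 6, 100), cfg)
  expect_true(ml2$valid)
  expect_true(all(diff(larvatrack:::cum_arc(ml2$points)) > 0))
})

test_that("overlong bodies fail tail-length validation", {
  m <- mask_body(w = 260, head = c(140, 100), tail_len = 85)
  body <- extract_full_body(m, c(140, 100))
  tp <- find_tail_tip(body, c(140, 100), 0, fx_cfg())
  ml <- compute_midline(tp, c(134, 100), fx_cfg())
  expect_gt(ml$length_mm, fx_cfg()$tail_length_max_mm)
  expect_false(ml$valid)
})

test_that("midline arc length is stable under rotation of the scene", {
  cfg <- fx_cfg()
  lay <- well_layout(1, radius_px = 100)
  lens <- vapply(c(0, 37, 90, 142), function(hd) {
    sc <- larva_script(1, x = lay$wells$cx, y = lay$wells$cy,
                       heading_deg = hd)
    vid <- render_video(lay, list(sc), 2, cfg, seed = 1, noise_sd = 0)
    tr <- track_well(vid, NULL, cfg, background = fx_background(lay))
    m <- tr$midline[, , 1, 1]
    sum(sqrt(rowSums(diff(m)^2)))
  }, 0)
  expect_lt(diff(range(lens)) / mean(lens), 0.02)
})

test_that("bend angle is signed, zero when straight, and antisymmetric", {
  # straight: tip collinear with the body axis
  ml <- cbind(seq(50, 10, length.out = 10), rep(20, 10))
  expect_equal(compute_bend_angle(ml, 0), 0, tolerance = 1e-10)

  # tip rotated 30 degrees off the tailward axis
  ang <- 30 * pi / 180
  tip <- c(50, 20) + 40 * c(-cos(ang), sin(ang))
  ml2 <- rbind(c(50, 20), tip)
  expect_equal(abs(compute_bend_angle(ml2, 0)), 30, tolerance = 1e-8)

  # mirroring the larva negates the angle exactly
  f <- fx_single_larva()
  tr <- fx_single_tracks()
  for (i in c(30, 60, 90)) {
    m <- tr$midline[, , i, 1]
    hd <- tr$heading[i, 1]
    mirrored <- cbind(m[, 1], 2 * 140 - m[, 2])   # reflect across y = 140
    expect_equal(compute_bend_angle(mirrored, -hd),
                 -compute_bend_angle(m, hd), tolerance = 1e-8)
  }
})

test_that("trace cleaning fills gaps and removes single-frame spikes", {
  cfg <- fx_cfg()
  expect_equal(clean_trace(rep(3, 50), cfg = cfg), rep(3, 50))

  sp <- rep(0, 50); sp[25] <- 50
  expect_true(all(clean_trace(sp, cfg = cfg)[3:48] == 0))

  lead <- c(NA, NA, NA, 5, 5, 5, 6, 6, 6, 7)
  out <- clean_trace(lead, cfg = cfg)
  expect_equal(out[1:3], rep(5, 3))
  expect_length(out, 10)

  gap <- c(1, 2, NA, NA, 5, 6, 7, 8, 9, 10)
  out2 <- clean_trace(gap, cfg = cfg)
  expect_false(anyNA(out2))
})

test_that("tracked bend angle and tip follow ground truth closely", {
  f <- fx_single_larva()
  tr <- fx_single_tracks()
  bend_err <- tr$bend_deg[, 1] - f$video$truth$bend_deg[, 1]
  expect_lt(sqrt(mean(bend_err^2)), 3)
  tip_err <- sqrt(rowSums((tr$tip[, , 1] - f$video$truth$tip[, , 1])^2))
  expect_lt(sqrt(mean(tip_err^2)), 3)
})
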