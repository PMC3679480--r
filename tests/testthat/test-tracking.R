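test_that("wells are detected where they were drawn", {
  lay <- well_layout(8, radius_px = 160, ncol = 4)
  bg <- fx_background(lay)
  wells <- detect_wells(bg, 8)
  expect_equal(nrow(wells), 8)
  # row-major order matches the layout; centres within 3 px
  for (k in 1:8) {
    expect_lt(abs(wells$cx[k] - lay$wells$cx[k]), 3)
    expect_lt(abs(wells$cy[k] - lay$wells$cy[k]), 3)
    expect_lt(abs(wells$r[k] - 160), 5)
  }
})

test_that("well detection reports count mismatches", {
  blank <- matrix(100L, 200, 200)
  expect_error(detect_wells(blank, 8), "0 circle")
  lay <- well_layout(1, radius_px = 80)
  w1 <- detect_wells(fx_background(lay), 1)
  expect_equal(nrow(w1), 1)
  expect_error(detect_wells(fx_background(lay), 3), "expected 3")
})

test_that("background estimation is the pixel-wise maximum", {
  f1 <- matrix(10L, 5, 5); f2 <- matrix(200L, 5, 5)
  expect_equal(estimate_background(list(f1, f2)), pmax(f1, f2))
  expect_equal(unique(as.vector(estimate_background(list(f1, f1)))), 10)
  expect_error(estimate_background(list()), "length")
})

test_that("a sweeping larva leaves a fully recovered background", {
  # the larva visits each column once; every pixel is larva-free in some
  # frame, so the maximum projection recovers the clean background exactly
  lay <- well_layout(1, radius_px = 100)
  cy <- lay$wells$cy
  n_fr <- 12
  path <- cbind(seq(lay$wells$cx - 60, lay$wells$cx + 60, length.out = n_fr),
                rep(cy, n_fr), rep(0, n_fr))
  vid <- render_video(lay, list(larva_script(1, path = path)), n_fr,
                      seed = 1, noise_sd = 0)
  bg_est <- estimate_background(vid$frames)
  expect_identical(bg_est, fx_background(lay))
})

test_that("double 3x3 erosion shrinks a 5x5 square to one pixel", {
  m <- matrix(0L, 11, 11); m[4:8, 4:8] <- 1L
  er <- larvatrack:::erode3x3(m, 2L)
  expect_equal(sum(er), 1)
  expect_equal(which(er == 1L, arr.ind = TRUE)[1, ], c(row = 6, col = 6))
})

test_that("core segmentation finds the larva and nothing else", {
  fs <- fx_single_frame()
  cfg <- fx_cfg()
  expect_length(fs$seg$cores, 1)
  co <- fs$seg$cores[[1]]
  expect_gte(co$area, cfg$core_area_min_px2)
  expect_lte(co$area, cfg$core_area_max_px2)
  gt <- fs$video$truth$core[1, , 1] - c(fs$x_off, fs$y_off)
  expect_lt(sqrt(sum((co$centroid - gt)^2)), 1)

  # identical frame and background give zero candidates
  bg <- fx_background(well_layout(1, radius_px = 120))
  seg0 <- segment_cores(bg, bg, cfg)
  expect_length(seg0$cores, 0)
})

test_that("raising the binarization threshold never grows a component", {
  fs <- fx_single_frame()
  cfg <- fx_cfg()
  prev_mask <- NULL
  for (thr in c(25, 50, 80, 120)) {
    cfg2 <- larva_config(binarize_threshold = thr)
    f <- fx_single_larva()
    crop <- larvatrack:::make_crop(f$video$frames[[1]], f$video$wells[1, ])
    seg <- segment_cores(crop(f$video$frames[[1]]), crop(f$background), cfg2)
    mask <- seg$binary > 0
    if (!is.null(prev_mask)) expect_true(all(prev_mask[mask]))
    prev_mask <- mask
  }
})

test_that("heading follows the principal axis of the moments", {
  # axis-aligned 3 x 11 rectangle: heading along x (0 or pi)
  pts <- as.matrix(expand.grid(x = 1:11, y = 1:3))
  th <- as.numeric(compute_heading(pts))
  expect_lt(min(abs(larvatrack:::wrap_pi(th - c(0, pi)))), 1e-6)

  # the same rectangle rotated by 30 degrees
  ang <- pi / 6
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  pr <- pts %*% t(R)
  th2 <- as.numeric(compute_heading(pr))
  err <- min(abs(larvatrack:::wrap_pi(th2 - c(ang, ang + pi))))
  expect_lt(err, pi / 180)
})

test_that("head-forward disambiguation points the right way", {
  # rendered larva facing +y (downward in image coordinates)
  cfg <- fx_cfg()
  lay <- well_layout(1, radius_px = 80)
  sc <- larva_script(1, x = lay$wells$cx, y = lay$wells$cy, heading_deg = 90)
  vid <- render_video(lay, list(sc), 2, cfg, seed = 1, noise_sd = 0)
  seg <- segment_cores(vid$frames[[1]], fx_background(lay), cfg)
  co <- seg$cores[[1]]
  th <- as.numeric(compute_heading(co$pixels, seg$diff[co$pixels]))
  expect_lt(abs(larvatrack:::wrap_pi(th - pi / 2)), 0.1)
})

test_that("identities follow constant-velocity prediction", {
  prev <- matrix(c(12, 10), 1); prev2 <- matrix(c(10, 10), 1)
  cand <- rbind(c(14, 10), c(50, 50))
  asg <- assign_identities(cand, prev, prev2)
  expect_equal(asg$match, 1L)
  expect_equal(asg$pred[1, ], c(14, 10))

  # zero candidates: carried over, invalid
  asg0 <- assign_identities(matrix(numeric(0), 0, 2), prev, prev2)
  expect_true(all(is.na(asg0$match)))
  expect_false(any(asg0$valid))

  # two larvae predicting the same candidate: collision flagged
  prevs <- rbind(c(10, 10), c(14, 10))
  cand1 <- matrix(c(12, 10), 1)
  asg2 <- assign_identities(cand1, prevs, prevs)
  expect_equal(nrow(asg2$collisions), 1)
  expect_equal(unlist(asg2$collisions[1, c("a", "b")]),
               c(a = 1L, b = 2L))
})

test_that("collision-free tracking keeps identities and accuracy", {
  cfg <- fx_cfg()
  n_fr <- 150
  lay <- well_layout(1, radius_px = 150)
  cx <- lay$wells$cx; cy <- lay$wells$cy
  mk <- function(k) {
    ph <- 2 * pi * k / 4 + seq(0, 0.5, length.out = n_fr)
    larva_script(1, path = cbind(cx + 90 * cos(ph), cy + 90 * sin(ph),
                                 (ph + pi / 2) * 180 / pi),
                 events = data.frame(start_ms = 60 + 40 * k,
                                     class = c("S", "T", "E", "S")[k + 1]))
  }
  vid <- render_video(lay, lapply(0:3, mk), n_fr, cfg, seed = 5,
                      noise_sd = 2)
  tr <- track_well(vid, vid$wells[1, ], cfg,
                   background = fx_background(lay))
  map <- fx_identity_map(tr, vid)
  expect_equal(sort(map), 1:4)     # bijective seeding
  for (j in 1:4) {
    err <- sqrt(rowSums((tr$core[, , j] - vid$truth$core[, , map[j]])^2))
    expect_lt(sqrt(mean(err^2)), 1)
    expect_lt(max(err), 3)         # no switch ever happened
    bend_err <- tr$bend_deg[, j] - vid$truth$bend_deg[, map[j]]
    expect_lt(sqrt(mean(bend_err^2)), 3)
  }
})
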