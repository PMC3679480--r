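test_that("degenerate and deterministic chains give exact indices", {
  # all-S: I(S -> S) = 1
  mv <- data.frame(well = 1, larva = rep(1:2, 5), onset_s = 1:10,
                   class = "S")
  ti <- transition_index(mv)
  expect_equal(ti$I["S", "S"], 1)
  expect_true(all(is.na(ti$I["T", ])))

  # strictly alternating S, T on one larva: I(S -> T) = 1 / 0.5 = 2
  mv2 <- data.frame(well = 1, larva = 1, onset_s = 1:10,
                    class = rep(c("S", "T"), 5))
  ti2 <- transition_index(mv2, "same")
  expect_equal(ti2$I["S", "T"], 2)
  expect_equal(ti2$I["S", "S"], 0)

  expect_equal(transition_index(mv2[1, , drop = FALSE])$n_pairs, 0)
})

test_that("the formula matches exhaustive pair enumeration", {
  cls <- c("S", "T", "E")
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    mv <- data.frame(well = 1, larva = sample(1:3, n, TRUE),
                     onset_s = sort(stats::runif(n, 0, 20)),
                     class = sample(cls, n, TRUE))
    ti <- transition_index(mv, "all")
    marg <- vapply(cls, function(cc) mean(mv$class == cc), 0)
    o <- mv[order(mv$onset_s), ]
    for (a in cls) for (b in cls) {
      den <- 0; num <- 0
      for (i in seq_len(n - 1)) if (o$class[i] == a) {
        den <- den + 1
        if (o$class[i + 1] == b) num <- num + 1
      }
      if (den > 0) expect_equal(ti$I[a, b], (num / den) / marg[[b]])
      else expect_true(is.na(ti$I[a, b]))
    }
  }
})

test_that("indices satisfy the conditional-probability identity", {
  mv <- simulate_maneuver_sequence(2000, seed = 7)
  for (v in c("all", "same", "different")) {
    ti <- transition_index(mv, v)
    for (r in 1:3) {
      if (all(is.na(ti$I[r, ]))) next
      # sum_B2 I(B1 -> B2) p(B2) = sum_B2 p(B2 | B1) = 1
      expect_equal(sum(ti$I[r, ] * ti$marginal), 1, tolerance = 1e-9)
    }
  }
})

test_that("random maneuver order drives every index to one", {
  mv <- simulate_maneuver_sequence(10000, seed = 13)
  ti <- transition_index(mv, "all")
  se <- sqrt((1 - ti$marginal) /
               (outer(rowSums(ti$counts), ti$marginal)))
  expect_true(all(abs(ti$I - 1) < pmax(3.5 * se, 0.02)))
})

test_that("a single all-covering window reproduces the plain index", {
  mv <- simulate_maneuver_sequence(1500, seed = 3)
  ti <- transition_index(mv, "all")
  wi <- windowed_index(mv, c(0, Inf), c(0, Inf), "all", min_count = 1,
                       successor_only = TRUE)
  cell <- matrix(wi$grid$I, 3, 3, byrow = TRUE,
                 dimnames = list(unique(wi$grid$b1), unique(wi$grid$b2)))
  expect_equal(wi$I_max[c("S", "T", "E"), c("S", "T", "E")],
               ti$I, tolerance = 1e-12)
})

test_that("larvae in different wells are never paired", {
  mv <- rbind(
    data.frame(well = 1, larva = 1:3, onset_s = c(1, 2, 3),
               x_mm = 0, y_mm = 0, class = c("S", "T", "E")),
    data.frame(well = 2, larva = 1:3, onset_s = c(1.5, 2.5, 3.5),
               x_mm = 0, y_mm = 0, class = c("E", "E", "E")))
  pr <- larvatrack:::windowed_pairs(
    larvatrack:::check_movements(mv), "all", Inf)
  wells_i <- mv$well[order(mv$well, mv$onset_s)][pr$i]
  wells_j <- mv$well[order(mv$well, mv$onset_s)][pr$j]
  expect_true(all(wells_i == wells_j))
})

test_that("planted pairwise enrichment is recovered with its p-value", {
  mv <- simulate_maneuver_sequence(
    8000, enrich = list(pair = c("E", "E"), time_s = 1, dist_mm = 5,
                        factor = 3, variant = "different"), seed = 17)
  wi <- windowed_index(mv, c(0, 1, 2, 4), c(0, 5, 10, 22), "different",
                       successor_only = TRUE)
  cell <- wi$grid[wi$grid$pair == "E-E" & wi$grid$t_hi == 1 &
                    wi$grid$d_hi == 5, ]
  expect_gt(cell$I, 2.3)
  pt <- permutation_test(mv, c("E", "E"), c(0, 1, 2, 4), c(0, 5, 10, 22),
                         "different", n_perm = 30, seed = 4,
                         successor_only = TRUE)
  expect_lt(pt$p_t, 0.01)
  expect_lte(pt$p_perm, 2 / 31)
  # determinism of the permutation sample
  pt2 <- permutation_test(mv, c("E", "E"), c(0, 1, 2, 4), c(0, 5, 10, 22),
                          "different", n_perm = 30, seed = 4,
                          successor_only = TRUE)
  expect_identical(pt$null, pt2$null)
})

test_that("input validation catches malformed movement tables", {
  expect_error(transition_index(data.frame(a = 1)), "lacks column")
  mv <- data.frame(well = 1, larva = 1, onset_s = 1, class = "X")
  expect_error(transition_index(mv), "unknown maneuver class")
  mv2 <- data.frame(well = 1, larva = 1:2, onset_s = 1:2,
                    class = c("S", "T"))
  expect_error(windowed_index(mv2, c(0, 1), c(0, 1)), "x_mm")
  expect_error(windowed_index(mv2, 1, c(0, 1)), "at least two")
})
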