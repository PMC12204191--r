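test_that("AOI assignment follows the half-open box convention", {
  lay <- default_retrieval_layout("left")
  expect_identical(assign_aoi(420, 810, lay), "target")   # centre of target
  expect_identical(assign_aoi(960, 270, lay), "cue")
  expect_identical(assign_aoi(5, 5, lay), "off")
  # left/top edges are inside, right/bottom edges are outside
  b <- lay$boxes$target
  expect_identical(assign_aoi(b[1], b[2], lay), "target")
  expect_identical(assign_aoi(b[3], 810, lay), "off")
  expect_identical(assign_aoi(420, b[4], lay), "off")
  expect_identical(assign_aoi(NA, 810, lay), "off")
})

test_that("entropy is exact on degenerate and uniform occupancy maps", {
  # all samples in one cell
  sm <- data.frame(x = rep(10, 50), y = rep(10, 50), valid = TRUE)
  expect_equal(gaze_entropy(sm, 80, 80, grid = c(8, 8), smoothing_sd = 0), 0)
  # exactly uniform over 64 cells
  centres <- expand.grid(x = 10 * (0:7) + 5, y = 10 * (0:7) + 5)
  sm <- data.frame(x = centres$x, y = centres$y, valid = TRUE)
  expect_equal(gaze_entropy(sm, 80, 80, grid = c(8, 8), smoothing_sd = 0), 6)
  # no valid samples -> undefined with a reason
  sm <- data.frame(x = 1, y = 1, valid = FALSE)
  h <- gaze_entropy(sm, 80, 80)
  expect_true(is.na(h))
  expect_match(attr(h, "reason"), "valid")
})

test_that("entropy matches the direct summation oracle on arbitrary histograms", {
  set.seed(12)
  for (rep in 1:5) {
    counts <- sample(1:40, 5)
    cells <- sample(0:63, 5)   # 8x8 grid cell ids
    xs <- unlist(mapply(function(c, n) rep(10 * (c %% 8) + 5, n),
                        cells, counts))
    ys <- unlist(mapply(function(c, n) rep(10 * (c %/% 8) + 5, n),
                        cells, counts))
    sm <- data.frame(x = xs, y = ys, valid = TRUE)
    p <- counts / sum(counts)
    expect_equal(gaze_entropy(sm, 80, 80, grid = c(8, 8), smoothing_sd = 0),
                 -sum(p * log2(p)), tolerance = 1e-12)
  }
})

test_that("heavy smoothing drives entropy monotonically toward the uniform bound", {
  sm <- data.frame(x = c(12, 15, 61), y = c(33, 35, 70), valid = TRUE)
  hs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(sd) {
    gaze_entropy(sm, 80, 80, grid = c(8, 8), smoothing_sd = sd)
  }, 0)
  expect_true(all(diff(hs) > -1e-9))
  expect_gt(hs[length(hs)], 0.97 * 6)
  expect_true(all(hs <= 6 + 1e-9))
})

test_that("hand-built trials produce the expected feature values", {
  lay <- default_retrieval_layout("left")
  # whole trial inside the target box, no saccades
  tr <- make_test_trial(data.frame(aoi = "target", duration = 2), lay)
  no_sacc <- data.frame(onset = numeric(0), offset = numeric(0),
                        x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                        y1 = numeric(0), amplitude = numeric(0),
                        peak_velocity = numeric(0),
                        mean_velocity = numeric(0))
  fix <- data.frame(onset = 0, offset = 2, duration = 2, x = 420, y = 810,
                    aoi_label = "target")
  f <- trial_features(tr, no_sacc, fix)
  expect_equal(f$dwell_target, 1)
  expect_equal(f$dwell_cue, 0)
  expect_identical(f$n_between_object_saccades, 0L)
  expect_equal(f$time_to_first_target_fixation, 0)
  expect_equal(f$trial_duration, 2, tolerance = 0.02)

  # 1 s on the cue then 1 s on the target with one connecting saccade
  tr2 <- make_test_trial(data.frame(aoi = c("cue", "target"),
                                    duration = c(1, 1)), lay)
  sacc <- data.frame(onset = 0.99, offset = 1.01, x0 = 960, y0 = 270,
                     x1 = 420, y1 = 810, amplitude = 10,
                     peak_velocity = 300, mean_velocity = 150)
  fix2 <- data.frame(onset = c(0, 1.01), offset = c(0.99, 2),
                     duration = c(0.99, 0.99), x = c(960, 420),
                     y = c(270, 810), aoi_label = c("cue", "target"))
  f2 <- trial_features(tr2, sacc, fix2)
  expect_equal(f2$dwell_cue, 0.5, tolerance = 0.02)
  expect_equal(f2$dwell_target, 0.5, tolerance = 0.02)
  expect_identical(f2$n_between_object_saccades, 1L)
  expect_equal(f2$time_to_first_target_fixation, 1.01)
  tr_excl <- tr2
  tr_excl$excluded <- TRUE
  tr_excl$exclusion_reason <- "invalid fraction 0.40 > 0.30"
  expect_error(trial_features(tr_excl, sacc, fix2), "excluded")
})

test_that("binned dwell ratios follow hand-computed values", {
  lay <- default_retrieval_layout("left")
  tr <- make_test_trial(data.frame(aoi = "target", duration = 1.5), lay)
  bd <- binned_dwell_ratios(tr)
  expect_equal(bd$target, rep(1, 6))
  expect_true(all(abs(bd$cue) < 1e-12))

  tr2 <- make_test_trial(data.frame(aoi = c("cue", "target"),
                                    duration = c(0.5, 0.5)), lay)
  bd2 <- binned_dwell_ratios(tr2)
  expect_equal(bd2$cue, c(1, 1, 0, 0), tolerance = 0.05)
  expect_equal(bd2$target, c(0, 0, 1, 1), tolerance = 0.05)

  # 40% off-AOI samples in a bin leave the ratios summing to 0.6
  tr3 <- make_test_trial(data.frame(aoi = "target", duration = 0.25), lay)
  off <- seq_len(10)                          # 10 of 25 samples off-screen
  tr3$samples$x[off] <- 5; tr3$samples$y[off] <- 5
  bd3 <- binned_dwell_ratios(tr3)
  expect_equal(bd3$cue + bd3$target + bd3$lure, 0.6, tolerance = 1e-12)
})

test_that("windowed features truncate events and duration at the cutoff", {
  lay <- default_retrieval_layout("left")
  tr <- make_test_trial(data.frame(aoi = c("cue", "target", "lure"),
                                   duration = c(1, 1, 1)), lay)
  sacc <- data.frame(onset = c(0.99, 1.99), offset = c(1.01, 2.01),
                     x0 = c(960, 420), y0 = c(270, 810),
                     x1 = c(420, 1500), y1 = c(810, 810),
                     amplitude = c(10, 14), peak_velocity = c(300, 400),
                     mean_velocity = c(150, 200))
  fix <- data.frame(onset = c(0, 1.01, 2.01), offset = c(0.99, 1.99, 3),
                    duration = c(0.99, 0.98, 0.99),
                    x = c(960, 420, 1500), y = c(270, 810, 810),
                    aoi_label = c("cue", "target", "lure"))
  full <- trial_features(tr, sacc, fix)
  w_big <- windowed_features(tr, sacc, fix, T = 10)
  expect_equal(w_big, full)
  w1 <- windowed_features(tr, sacc, fix, T = 1)
  expect_identical(w1$n_saccades, 1L)
  expect_equal(w1$trial_duration, 1)
  expect_equal(w1$dwell_cue, 1, tolerance = 0.03)
})

test_that("correct trials dwell more on the target than the lure at cohort scale", {
  f <- small_analysis()$features
  cc <- f$condition == "correct"
  expect_gt(mean(f$dwell_target[cc]), mean(f$dwell_lure[cc]))
  expect_gt(mean(f$dwell_lure[!cc]), mean(f$dwell_target[!cc]))
})
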