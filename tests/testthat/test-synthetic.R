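test_that("cohort generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_hc = 1, n_tle = 1, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("generated streams have exact sample spacing and stay on screen", {
  coh <- small_cohort()
  cfg <- coh$config
  for (tr in coh$sessions[[1]]$trials[c(1, 61, 90, 150)]) {
    dt <- diff(tr$samples$t)
    expect_true(all(dt > 0))
    expect_equal(dt, rep(1 / cfg$sampling_rate, length(dt)),
                 tolerance = 1e-12)
    ok <- tr$samples$valid
    expect_true(all(tr$samples$x[ok] >= 0 & tr$samples$x[ok] < cfg$screen_w))
    expect_true(all(tr$samples$y[ok] >= 0 & tr$samples$y[ok] < cfg$screen_h))
  }
})

test_that("ground truth tiles the trial and counts the rendered ramps", {
  coh <- small_cohort()
  gts <- coh$ground_truth[[2]]
  for (gt in gts[61:80]) {
    expect_identical(gt$n_saccades, nrow(gt$saccades))
    expect_true(all(diff(gt$saccades$onset) > 0))
    expect_true(all(gt$saccades$offset > gt$saccades$onset))
    # schedule alternates fixation / saccade without gaps or overlap
    n <- nrow(gt$fixations)
    expect_equal(gt$fixations$offset[-n], gt$saccades$onset, tolerance = 1e-9)
    expect_equal(gt$saccades$offset, gt$fixations$onset[-1], tolerance = 1e-9)
    expect_identical(gt$fixations$aoi[1], "cue")
    expect_true("target" %in% gt$fixations$aoi)
  }
})

test_that("a blink-free configuration yields fully valid samples", {
  cfg <- sim_config(n_hc = 1, n_tle = 0, seed = 5,
                    blink = list(rate_hz = 0, dur_min_s = 0.1,
                                 dur_max_s = 0.3, dropout_prob = 0))
  coh <- generate_cohort(cfg)
  valid <- unlist(lapply(coh$sessions[[1]]$trials,
                         function(tr) tr$samples$valid))
  expect_true(all(valid))
})

test_that("true saccade counts match the configured mean (law of large numbers)", {
  cfg <- sim_config(seed = 9)
  mu <- cfg$groups$TLE$saccade_count_mean_correct
  size <- cfg$groups$TLE$saccade_count_dispersion
  set.seed(31)
  counts <- vapply(seq_len(300), function(i) {
    generate_trial(list(phase = "retrieval", group = "TLE",
                        condition = "correct"),
                   cfg)$ground_truth$n_saccades
  }, 0L)
  se <- sqrt(mu + mu^2 / size) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 2 * se + 0.1)
})

test_that("correct trials prefer the target in the late time bins by construction", {
  cfg <- sim_config(seed = 13)
  set.seed(17)
  dwell <- matrix(0, 2, 2, dimnames = list(c("target", "lure"),
                                           c("early", "late")))
  for (i in seq_len(120)) {
    gt <- generate_trial(list(phase = "retrieval", group = "HC",
                              condition = "correct"), cfg)$ground_truth
    fx <- gt$fixations
    for (j in seq_len(nrow(fx))) {
      if (!fx$aoi[j] %in% c("target", "lure")) next
      lo <- fx$onset[j]; hi <- fx$offset[j]
      dwell[fx$aoi[j], "late"] <- dwell[fx$aoi[j], "late"] +
        max(0, hi - max(lo, 1.0))
      dwell[fx$aoi[j], "early"] <- dwell[fx$aoi[j], "early"] +
        max(0, min(hi, 1.0) - lo)
    }
  }
  expect_gt(dwell["target", "late"], dwell["lure", "late"])
})

test_that("pupil kernel has the designed biphasic shape", {
  pp <- sim_config()$pupil
  expect_lt(abs(pupil_response_kernel(0, pp)), 0.005)
  expect_identical(pupil_response_kernel(c(0, 0.3, 1), list(
    baseline_mm = 3.5, drift_sd = 0, constriction_amp = 0,
    constriction_latency_s = 0.25, constriction_width_s = 0.09,
    dilation_amp = 0, dilation_peak_s = 0.8,
    target_correct_dilation_boost = 1)), c(0, 0, 0))
  # constriction lobe alone bottoms out at the configured latency
  tt <- seq(0, 1.5, by = 0.001)
  pp0 <- pp; pp0$dilation_amp <- 0
  expect_lt(abs(tt[which.min(pupil_response_kernel(tt, pp0))] -
                  pp$constriction_latency_s), 0.0015)
  # full kernel: minimum early, maximum later (constriction then dilation)
  k <- pupil_response_kernel(tt, pp)
  expect_lt(tt[which.min(k)], 0.35)
  expect_gt(tt[which.max(k)], 0.5)
  # dilation boost scales the positive lobe only
  kb <- pupil_response_kernel(tt, pp, boost = 2)
  expect_gt(max(kb), max(k))
})

test_that("simulated responder policies behave as specified", {
  gt_correct <- list(condition = "correct")
  gt_incorrect <- list(condition = "incorrect")
  set.seed(2)
  acc <- mean(vapply(seq_len(10000), function(i) {
    simulate_responder(gt_correct, "random")$choice == "target"
  }, TRUE))
  expect_lt(abs(acc - 0.5), 0.01)
  expect_identical(simulate_responder(gt_correct, "always_target")$choice,
                   "target")
  expect_identical(
    simulate_responder(gt_correct, "schedule_consistent")$choice, "target")
  expect_identical(
    simulate_responder(gt_incorrect, "schedule_consistent")$choice, "lure")
  expect_error(simulate_responder(gt_correct, "telepathy"))
  rsp <- simulate_responder(gt_correct, "always_target", duration = 3.2)
  expect_identical(rsp$response_time, 3.2)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(sampling_rate = 60), "sampling_rate")
  expect_error(sim_config(groups = list(HC = list(direct_accuracy_mean = 1.2))),
               "direct_accuracy_mean")
  expect_error(sim_config(conditions = list(correct = list(
    trial_duration_mean = -1))), "trial_duration_mean")
  expect_error(sim_config(blink = list(dur_min_s = 0)), "dur_min_s")
})

test_that("schedule-consistent responders reproduce the configured accuracy", {
  coh <- fixture("acc_cohort", {
    generate_cohort(sim_config(n_hc = 6, n_tle = 0, seed = 21,
                               indirect_accuracy_offset = 0))
  })
  gts <- unlist(lapply(coh$ground_truth, function(g) {
    vapply(g, function(gt) gt$condition, "")
  }))
  gts <- gts[gts %in% c("correct", "incorrect")]
  acc <- mean(gts == "correct")
  # binomial + between-subject spread around the configured mean
  expect_lt(abs(acc - 0.90), 3 * sqrt(0.9 * 0.1 / length(gts)) + 0.07)
})
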