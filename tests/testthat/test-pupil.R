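zsession <- function() fixture("zsession", {
  zscore_session(small_cohort()$sessions[[1]])
})

test_that("session z-scoring standardises valid pupil samples", {
  ses <- zsession()
  vals <- unlist(lapply(ses$trials, function(tr) {
    tr$samples$pupil_z[tr$samples$valid]
  }))
  vals <- vals[is.finite(vals)]
  expect_lt(abs(mean(vals)), 1e-9)
  expect_lt(abs(sd(vals) - 1), 1e-9)
})

test_that("z-scoring is invariant to positive affine transforms", {
  ses <- small_cohort()$sessions[[1]]
  scaled <- ses
  scaled$trials <- lapply(ses$trials, function(tr) {
    tr$samples$pupil <- 2.5 * tr$samples$pupil + 1.3
    tr
  })
  a <- zscore_session(ses)
  b <- zscore_session(scaled)
  expect_equal(a$trials[[70]]$samples$pupil_z,
               b$trials[[70]]$samples$pupil_z, tolerance = 1e-9)
})

test_that("constant pupil is a zero-variance error", {
  ses <- small_cohort()$sessions[[1]]
  flat <- ses
  flat$trials <- lapply(ses$trials, function(tr) {
    tr$samples$pupil[] <- 3.5
    tr
  })
  expect_error(zscore_session(flat), "variance")
})

# A trial with isolated injected kernels at known times.
kernel_trial <- function(events = c(1, 4, 7), total = 10, rate = 100,
                         noise_sd = 0.02, seed = 6) {
  set.seed(seed)
  pp <- sim_config()$pupil
  t <- (seq_len(total * rate) - 1) / rate
  pupil <- 3.5 + rnorm(length(t), 0, noise_sd)
  for (e in events) pupil <- pupil + pupil_response_kernel(t - e, pp)
  structure(list(subject_id = "K", trial_id = 1L, phase = "retrieval",
                 trial_type = "direct", block = 1L, condition = "correct",
                 group = "HC", aoi = default_retrieval_layout(),
                 samples = data.frame(t = t, x = 960, y = 270, pupil = pupil,
                                      valid = TRUE),
                 response_time = total, excluded = FALSE),
            class = "gaze_trial")
}

test_that("epoch extraction drops out-of-bounds events and conserves counts", {
  tr <- kernel_trial()
  ses <- structure(list(subject_id = "K", group = "HC", sampling_rate = 100,
                        trials = list(tr), metadata = list()),
                   class = "gaze_session")
  ses <- zscore_session(ses)
  tr <- ses$trials[[1]]
  events <- c(0.1, 1, 4, 7, 9.9)      # first and last exceed the window
  ep <- extract_epochs(tr, events)
  expect_identical(nrow(ep$epochs) + ep$n_dropped, length(events))
  expect_identical(ep$n_dropped, 2L)
  expect_equal(range(ep$grid), c(-0.25, 1.25))
})

test_that("epoch averages recover an injected kernel", {
  pp <- sim_config()$pupil
  events <- seq(1, 55, by = 3)
  tr <- kernel_trial(events = events, total = 58, noise_sd = 0.02)
  ses <- structure(list(subject_id = "K", group = "HC", sampling_rate = 100,
                        trials = list(tr), metadata = list()),
                   class = "gaze_session")
  ses <- zscore_session(ses)
  ztr <- ses$trials[[1]]
  ep <- extract_epochs(ztr, events)
  avg <- colMeans(ep$epochs)
  # oracle: the injected kernel mapped through the session z-transform
  mu <- ses$pupil_stats["mean"]; sdv <- ses$pupil_stats["sd"]
  want <- (3.5 + pupil_response_kernel(ep$grid, pp) - mu) / sdv
  se <- apply(ep$epochs, 2, sd) / sqrt(nrow(ep$epochs))
  expect_lt(max(abs(avg - want)), max(3 * max(se), 0.15))
  # biphasic shape: minimum before 0.3 s, maximum after
  expect_lt(ep$grid[which.min(avg)], 0.3)
  expect_gt(ep$grid[which.max(avg)], 0.3)
})

test_that("z-scoring commutes with epoch extraction", {
  events <- c(1, 4, 7)
  tr_raw <- kernel_trial(events = events)
  ses <- structure(list(subject_id = "K", group = "HC", sampling_rate = 100,
                        trials = list(tr_raw), metadata = list()),
                   class = "gaze_session")
  zs <- zscore_session(ses)
  ep_z <- extract_epochs(zs$trials[[1]], events)
  # extract raw epochs, then standardise with the session statistics
  tr2 <- tr_raw
  tr2$samples$pupil_z <- tr2$samples$pupil
  ep_raw <- extract_epochs(tr2, events)
  manual <- (ep_raw$epochs - zs$pupil_stats["mean"]) / zs$pupil_stats["sd"]
  expect_equal(ep_z$epochs, manual, tolerance = 1e-9)
})

test_that("condition averages equal brute-force pointwise means", {
  set.seed(8)
  ep <- matrix(rnorm(60), 6, 10)
  ep[1, 3] <- NA; ep[2, 3] <- NA; ep[3, 3] <- NA; ep[4, 3] <- NA
  grid <- seq(0, 0.9, by = 0.1)
  groups <- rep(c("a", "b"), each = 3)
  avg <- condition_average(ep, grid, groups)
  for (g in c("a", "b")) {
    rows <- ep[groups == g, ]
    got <- avg$mean[avg$group == g]
    for (j in seq_len(10)) {
      defined <- sum(is.finite(rows[, j]))
      if (defined < nrow(rows) / 2) {
        expect_true(is.na(got[j]))
      } else {
        expect_equal(got[j], mean(rows[, j], na.rm = TRUE))
      }
    }
  }
  # identical epochs: mean is the epoch, dispersion zero
  same <- matrix(rep(ep[5, ], 3), 3, byrow = TRUE)
  avg1 <- condition_average(same, grid, rep("x", 3))
  expect_equal(avg1$mean, ep[5, ])
  expect_equal(avg1$sem, rep(0, 10))
  # two epochs: mean is their midpoint trace
  two <- ep[5:6, ]
  avg2 <- condition_average(two, grid, rep("y", 2))
  expect_equal(avg2$mean, (two[1, ] + two[2, ]) / 2)
  expect_warning(condition_average(ep[0, , drop = FALSE], grid,
                                   character(0)), NA)
})

test_that("target-saccade pupil dilation separates correct from incorrect trials", {
  coh <- fixture("pupil_cohort", {
    generate_cohort(sim_config(n_hc = 4, n_tle = 4, seed = 55))
  })
  res <- pupil_condition_contrast(coh$sessions, screen_geometry(),
                                  n_perm = 200, seed = 9)
  avg <- res$average
  a <- avg[avg$group == "correct", ]
  b <- avg[avg$group == "incorrect", ]
  late <- a$t > 0.5 & a$t < 1.1
  # correct trials carry the boosted dilation
  expect_gt(mean(a$mean[late], na.rm = TRUE),
            mean(b$mean[late], na.rm = TRUE))
  # and the cluster test localises a significant difference
  sig <- res$cluster$clusters[res$cluster$clusters$p < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$end > 0.4))
})
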