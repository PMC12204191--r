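# Hand-built stream with sigmoidal ramps at known onsets, no noise.
ramp_stream <- function(onsets, amp_px = 400, dur = 0.04, rate = 120,
                        total = NULL, x0 = 200) {
  total <- total %||% (max(onsets) + 0.5)
  m <- round(total * rate)
  t <- (seq_len(m) - 1) / rate
  x <- rep(x0, m)
  level <- x0
  sig <- function(u) 1 / (1 + exp(-12 * (u - 0.5)))
  for (on in onsets) {
    during <- t > on & t < on + dur
    after <- t >= on + dur
    x[during] <- level + amp_px * sig((t[during] - on) / dur)
    x[after] <- level + amp_px
    level <- level + amp_px
  }
  data.frame(t = t, x = x, y = 540, pupil = 3.5, valid = TRUE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("velocity is zero for stationary gaze and matches a linear ramp", {
  g <- screen_geometry()
  still <- data.frame(t = (0:99) / 100, x = 500, y = 300, valid = TRUE)
  v <- compute_velocity(still, g)
  expect_true(all(abs(v$speed[3:98]) < 1e-9))

  ramp <- data.frame(t = (0:99) / 100, x = 100 + 100 * (0:99) / 100,
                     y = 300, valid = TRUE)
  v <- compute_velocity(ramp, g)
  expect_equal(v$vx[3:98], rep(100 * g$deg_per_px_x, 96), tolerance = 1e-9)
  expect_equal(v$speed[3:98], rep(100 * g$deg_per_px_x, 96),
               tolerance = 1e-9)
})

test_that("time reversal negates velocity components but preserves speed", {
  g <- screen_geometry()
  set.seed(4)
  sm <- data.frame(t = (0:199) / 120, x = cumsum(rnorm(200, 0, 5)) + 900,
                   y = cumsum(rnorm(200, 0, 5)) + 500, valid = TRUE)
  rev_sm <- sm
  rev_sm$x <- rev(sm$x); rev_sm$y <- rev(sm$y)
  v <- compute_velocity(sm, g)
  vr <- compute_velocity(rev_sm, g)
  i <- 3:198
  expect_equal(vr$vx[i], -rev(v$vx)[i], tolerance = 1e-9)
  expect_equal(vr$vy[i], -rev(v$vy)[i], tolerance = 1e-9)
  expect_equal(vr$speed[i], rev(v$speed)[i], tolerance = 1e-9)
})

test_that("fewer than five samples is an error", {
  g <- screen_geometry()
  expect_error(compute_velocity(
    data.frame(t = (0:3) / 100, x = 1, y = 1, valid = TRUE), g), "5 samples")
})

test_that("a zero-velocity trace yields no saccades", {
  g <- screen_geometry()
  still <- data.frame(t = (0:199) / 120, x = 500, y = 300, valid = TRUE)
  v <- compute_velocity(still, g)
  expect_identical(nrow(detect_saccades(v, still, g)), 0L)
})

test_that("injected ramps are each detected once with onsets at ground truth", {
  g <- screen_geometry()
  onsets <- c(0.3, 0.7, 1.1, 1.5, 1.9, 2.3, 2.7)
  sm <- ramp_stream(onsets, amp_px = 300, total = 3.2)
  v <- compute_velocity(sm, g)
  sac <- detect_saccades(v, sm, g)
  expect_identical(nrow(sac), 7L)
  expect_true(all(abs(sac$onset - onsets) <= 1 / 120 + 1e-9))
  expect_true(all(sac$amplitude > 2))
})

test_that("candidates separated by less than the merge interval fuse", {
  g <- screen_geometry()
  # 1 kHz stream so the 10-ms inter-ramp gap is resolvable by the stencil
  sm <- ramp_stream(c(0.4, 0.45), amp_px = 300, dur = 0.04, rate = 1000,
                    total = 1)
  v <- compute_velocity(sm, g)
  sac <- detect_saccades(v, sm, g,
                         event_params(merge_interval = 0.020))
  expect_identical(nrow(sac), 1L)
  # with a tiny merge interval the same stream gives two events
  sac2 <- detect_saccades(v, sm, g, event_params(merge_interval = 0.001))
  expect_identical(nrow(sac2), 2L)
})

test_that("the adaptive threshold is invariant to constant position offsets", {
  g <- screen_geometry()
  sm <- ramp_stream(c(0.3, 0.9), amp_px = 300, total = 1.4)
  shifted <- sm
  shifted$x <- sm$x + 500
  a <- detect_saccades(compute_velocity(sm, g), sm, g)
  b <- detect_saccades(compute_velocity(shifted, g), shifted, g)
  expect_equal(a$onset, b$onset)
  expect_equal(a$offset, b$offset)
})

test_that("fixations fill inter-saccade intervals and respect the minimum duration", {
  g <- screen_geometry()
  lay <- default_retrieval_layout()
  still <- data.frame(t = (0:199) / 120, x = 420, y = 810, valid = TRUE)
  fix <- detect_fixations(still, detect_saccades(compute_velocity(still, g),
                                                 still, g), lay)
  expect_identical(nrow(fix), 1L)
  expect_equal(fix$onset, 0)
  expect_equal(fix$offset, still$t[200])
  expect_identical(fix$aoi_label, "target")

  # an inter-saccade interval shorter than the minimum emits no fixation
  sacc <- data.frame(onset = c(0.5, 0.56), offset = c(0.54, 0.6),
                     x0 = 1, y0 = 1, x1 = 2, y1 = 2)
  fix <- detect_fixations(still, sacc, lay,
                          event_params(min_fixation_duration = 0.05))
  expect_true(all(fix$duration >= 0.05))
  expect_false(any(fix$onset >= 0.53 & fix$offset <= 0.57))
})

test_that("the detector recovers the generated fixation AOI sequence", {
  cfg <- sim_config(seed = 3, blink = list(rate_hz = 0, dropout_prob = 0))
  g <- screen_geometry()
  set.seed(41)
  ok <- 0L
  for (i in 1:20) {
    tr <- generate_trial(list(phase = "retrieval", group = "HC",
                              condition = "correct"), cfg)
    rec <- structure(list(subject_id = "X", trial_id = i, aoi = tr$layout,
                          samples = tr$samples, condition = "correct",
                          phase = "retrieval", excluded = FALSE),
                     class = "gaze_trial")
    ev <- detect_events(rec, g)
    collapse <- function(v) v[c(TRUE, v[-1] != v[-length(v)])]
    got <- collapse(ev$fixations$aoi_label[ev$fixations$aoi_label != "off"])
    want <- collapse(tr$ground_truth$fixations$aoi)
    if (identical(got, want)) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("detected counts track injected counts over many trials", {
  cfg <- sim_config(seed = 3, blink = list(rate_hz = 0, dropout_prob = 0))
  g <- screen_geometry()
  set.seed(99)
  err <- vapply(seq_len(150), function(i) {
    grp <- sample(c("HC", "TLE"), 1)
    tr <- generate_trial(list(phase = "retrieval", group = grp,
                              condition = sample(c("correct", "incorrect"), 1)),
                         cfg)
    v <- compute_velocity(tr$samples, g)
    sac <- detect_saccades(v, tr$samples, g)
    abs(nrow(sac) - tr$ground_truth$n_saccades)
  }, 0)
  expect_gte(mean(err <= 1), 0.95)
})
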