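#' Post-saccadic pupil response kernel
#'
#' Deterministic pupil deflection added after every saccade: a transient
#' constriction (negative Gaussian lobe centred at
#' `constriction_latency_s`) followed by a slower dilation (gamma-shaped
#' positive lobe peaking at `dilation_peak_s`). When `boost` differs from 1
#' the dilation lobe is scaled by it, which the generator uses for saccades
#' landing on the target during correct trials.
#'
#' @param t Time in seconds relative to saccade initiation (vectorised).
#' @param params Pupil block of a [sim_config()].
#' @param boost Multiplier on the dilation amplitude.
#' @return Pupil deflection in mm; 0 for `t < 0`.
#' @examples
#' k <- pupil_response_kernel(seq(0, 1.5, by = 0.01), sim_config()$pupil)
#' range(k)
#' @export
pupil_response_kernel <- function(t, params, boost = 1) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  constr <- -params$constriction_amp *
    exp(-((tp - params$constriction_latency_s)^2) /
          (2 * params$constriction_width_s^2))
  # gamma-shaped lobe t^a exp(-t/theta), normalised to peak 1 at a * theta
  a <- 2
  theta <- params$dilation_peak_s / a
  peak_val <- (params$dilation_peak_s / theta)^a * exp(-a)
  dil <- boost * params$dilation_amp *
    (tp / theta)^a * exp(-tp / theta) / peak_val
  out[pos] <- constr + dil
  out
}

# Sigmoidal displacement profile of a saccade, u in [0, 1] -> [0, 1].
saccade_profile <- function(u) {
  lo <- stats::plogis(-6)
  hi <- stats::plogis(6)
  (stats::plogis(12 * (u - 0.5)) - lo) / (hi - lo)
}

# Draw a landing point inside an AOI box: centre + isotropic Gaussian
# scatter, clipped to an inner margin. If the previous fixation sat in the
# same box closer than `min_dist`, the point is pushed to `min_dist` along a
# direction that stays inside the box, so every rendered saccade has a
# resolvable amplitude.
draw_fix_point <- function(box, jitter_sd, prev = NULL, min_dist = 0,
                           margin = 15) {
  cx <- (box[1] + box[3]) / 2
  cy <- (box[2] + box[4]) / 2
  lo <- c(box[1] + margin, box[2] + margin)
  hi <- c(box[3] - margin, box[4] - margin)
  clip <- function(p) pmin(pmax(p, lo), hi)
  p <- clip(c(cx, cy) + stats::rnorm(2, 0, jitter_sd))
  if (!is.null(prev) && min_dist > 0) {
    tries <- 0L
    while (sqrt(sum((p - prev)^2)) < min_dist && tries < 30L) {
      p <- clip(c(cx, cy) + stats::rnorm(2, 0, jitter_sd))
      tries <- tries + 1L
    }
    if (sqrt(sum((p - prev)^2)) < min_dist) {
      # deterministic fallback: walk toward the farthest inner corner
      corners <- rbind(lo, c(lo[1], hi[2]), c(hi[1], lo[2]), hi)
      d <- sqrt(rowSums((corners - rep(prev, each = 4))^2))
      dir <- corners[which.max(d), ] - prev
      dir <- dir / sqrt(sum(dir^2))
      p <- clip(prev + dir * min_dist)
    }
  }
  p
}

# AOI-choice weights at time `tt` (s) from a per-250-ms-bin curve matrix.
curve_weights <- function(curve, tt) {
  i <- min(nrow(curve), 1L + floor(max(tt, 0) / 0.25))
  w <- curve[i, ]
  names(w) <- colnames(curve)
  w
}

#' Generate one synthetic trial
#'
#' Renders the gaze and pupil stream of a single trial together with its
#' ground truth. Retrieval trials start with a fixation on the cue, visit the
#' target for the first time at a latency drawn from the group's
#' first-target-fixation distribution, and afterwards hop between AOIs under
#' the condition's time-varying preference curve. Saccades are sigmoidal
#' position ramps whose duration follows the main-sequence rule
#' 21 ms + 2.2 ms/deg. The pupil trace is a drifting baseline plus one
#' [pupil_response_kernel()] per saccade. Blinks and tracker dropouts are
#' marked invalid.
#'
#' @param trial_spec List with fields `phase` (`"exposure"` or
#'   `"retrieval"`), `group` (`"HC"`/`"TLE"`), `condition` (`"correct"`,
#'   `"incorrect"`, or `"n.a."` for exposure), `layout` (an [aoi_layout()];
#'   defaults to the standard layout), and optional multipliers
#'   `count_mult`, `dur_mult` (per-subject heterogeneity).
#' @param config A [sim_config()].
#' @param seed Optional seed for a self-contained reproducible draw; when
#'   `NULL` the current RNG stream is used (as inside [generate_cohort()]).
#' @return List with `samples` (data.frame `t, x, y, pupil, valid`),
#'   `ground_truth` (fixation schedule, saccade table, pupil events,
#'   condition) and `duration` (s).
#' @export
generate_trial <- function(trial_spec, config, seed = NULL) {
  with_seed(seed, {
    if (identical(trial_spec$phase, "exposure")) {
      generate_exposure_trial(trial_spec, config)
    } else {
      generate_retrieval_trial(trial_spec, config)
    }
  })
}

generate_retrieval_trial <- function(spec, config) {
  grp <- config$groups[[spec$group]]
  cond <- config$conditions[[spec$condition]]
  if (is.null(grp)) stopf("generate_trial: unknown group '%s'", spec$group)
  if (is.null(cond)) stopf("generate_trial: unknown condition '%s'",
                           spec$condition)
  layout <- spec$layout %||% default_retrieval_layout(
    sample(c("left", "right"), 1), config$screen_w, config$screen_h)
  geom <- config_geometry(config)
  rate <- config$sampling_rate
  count_mult <- spec$count_mult %||% 1
  dur_mult <- spec$dur_mult %||% 1

  count_mean <- switch(spec$condition,
                       correct = grp$saccade_count_mean_correct,
                       incorrect = grp$saccade_count_mean_incorrect)
  D <- rnorm_trunc(1, cond$trial_duration_mean * dur_mult,
                   cond$trial_duration_sd, lower = 0.8)
  # latency is truncated to the trial rather than the trial stretched to the
  # latency, which would bias the realised duration distribution upward
  L <- rnorm_trunc(1, grp$first_target_fixation_latency_mean,
                   grp$first_target_fixation_latency_sd,
                   lower = 0.2, upper = max(0.25, 0.6 * D))
  # saccade count scales with the realised duration within the trial (longer
  # scanning accumulates more saccades), keeping the count marginally at the
  # configured mean while making count/duration combinations feasible
  rel_dur <- D / (cond$trial_duration_mean * dur_mult)
  n_sacc <- max(2L, stats::rnbinom(1, size = grp$saccade_count_dispersion,
                                   mu = count_mean * count_mult *
                                     sqrt(max(rel_dur, 0.1))))
  k_pre_est <- max(1L, as.integer(round(L / 0.32)))
  n_cap <- k_pre_est + max(1L, as.integer(floor((D - L - 0.06) / 0.105)))
  n_sacc <- max(2L, min(n_sacc, n_cap))

  n_fix <- n_sacc + 1L
  k_pre <- max(1L, min(n_sacc - 1L, as.integer(round(L / 0.32))))
  target_idx <- k_pre + 1L

  curve <- cond$target_dwell_bias_curve
  aoi_seq <- character(n_fix)
  aoi_seq[1] <- "cue"
  if (k_pre >= 2L) {
    for (i in 2:k_pre) {
      w <- curve_weights(curve, (i - 1) * L / k_pre)
      w <- w[c("cue", "lure")]
      aoi_seq[i] <- sample(c("cue", "lure"), 1, prob = w / sum(w))
    }
  }
  aoi_seq[target_idx] <- "target"
  if (target_idx < n_fix) {
    est_fix <- (D - L) / (n_fix - k_pre)
    for (i in (target_idx + 1L):n_fix) {
      w <- curve_weights(curve, L + (i - target_idx) * est_fix)
      aoi_seq[i] <- sample(colnames(curve), 1, prob = w / sum(w))
    }
  }

  jit <- grp$spatial_jitter_sd
  pts <- matrix(0, n_fix, 2)
  pts[1, ] <- draw_fix_point(layout$boxes[[aoi_seq[1]]], jit)
  for (i in 2:n_fix) {
    prev <- if (aoi_seq[i] == aoi_seq[i - 1]) pts[i - 1, ] else NULL
    pts[i, ] <- draw_fix_point(layout$boxes[[aoi_seq[i]]], jit, prev = prev,
                               min_dist = config$min_refixation_dist)
  }

  amp <- px_dist_deg(pts[-n_fix, 1], pts[-n_fix, 2],
                     pts[-1, 1], pts[-1, 2], geom)
  sacc_dur <- 0.021 + 0.0022 * amp

  # fixation durations: pre-target block sums (with its saccades) to L,
  # post block fills the remainder of the trial
  min_fix <- 0.06
  pre_sacc <- sum(sacc_dur[seq_len(k_pre)])
  if (L < pre_sacc + min_fix * k_pre) L <- pre_sacc + min_fix * k_pre + 0.02
  post_sacc <- sum(sacc_dur) - pre_sacc
  if (D < L + post_sacc + min_fix * (n_fix - k_pre)) {
    D <- L + post_sacc + min_fix * (n_fix - k_pre) + 0.05
  }
  alloc <- function(total, k) {
    raw <- stats::rgamma(k, shape = 3, rate = 1)
    min_fix + raw / sum(raw) * (total - min_fix * k)
  }
  fix_dur <- numeric(n_fix)
  fix_dur[seq_len(k_pre)] <- alloc(L - pre_sacc, k_pre)
  fix_dur[(k_pre + 1L):n_fix] <- alloc(D - L - post_sacc, n_fix - k_pre)

  build_trial_stream(pts, aoi_seq, fix_dur, sacc_dur, amp, D,
                     condition = spec$condition, config = config,
                     layout = layout)
}

generate_exposure_trial <- function(spec, config) {
  layout <- spec$layout %||%
    default_exposure_layout(config$screen_w, config$screen_h)
  geom <- config_geometry(config)
  n_sacc <- 1L + stats::rpois(1, config$exposure$n_saccades_mean - 1)
  n_fix <- n_sacc + 1L
  D <- 1.0
  aoi_seq <- rep(c("left", "right"), length.out = n_fix)
  if (stats::runif(1) < 0.5) aoi_seq <- rev(aoi_seq)
  jit <- config$exposure$spatial_jitter_sd
  pts <- matrix(0, n_fix, 2)
  pts[1, ] <- draw_fix_point(layout$boxes[[aoi_seq[1]]], jit)
  for (i in 2:n_fix) {
    pts[i, ] <- draw_fix_point(layout$boxes[[aoi_seq[i]]], jit)
  }
  amp <- px_dist_deg(pts[-n_fix, 1], pts[-n_fix, 2],
                     pts[-1, 1], pts[-1, 2], geom)
  sacc_dur <- 0.021 + 0.0022 * amp
  min_fix <- 0.07
  total_fix <- D - sum(sacc_dur)
  if (total_fix < min_fix * n_fix) {
    # too many saccades drawn for a 1-s trial: redraw
    return(generate_exposure_trial(
      list(phase = "exposure", layout = layout), config))
  }
  raw <- stats::rgamma(n_fix, shape = 3, rate = 1)
  fix_dur <- min_fix + raw / sum(raw) * (total_fix - min_fix * n_fix)
  build_trial_stream(pts, aoi_seq, fix_dur, sacc_dur, amp, D,
                     condition = "n.a.", config = config, layout = layout)
}

# Render the sample stream from a fixation/saccade schedule and assemble the
# ground truth. Schedule: fix 1, sacc 1, fix 2, ..., sacc n, fix n+1.
build_trial_stream <- function(pts, aoi_seq, fix_dur, sacc_dur, amp, D,
                               condition, config, layout) {
  n_fix <- length(fix_dur)
  n_sacc <- n_fix - 1L
  rate <- config$sampling_rate
  seg_dur <- numeric(2L * n_fix - 1L)
  seg_dur[seq(1, by = 2, length.out = n_fix)] <- fix_dur
  if (n_sacc > 0) seg_dur[seq(2, by = 2, length.out = n_sacc)] <- sacc_dur
  bounds <- c(0, cumsum(seg_dur))
  D <- bounds[length(bounds)]

  fix_on <- bounds[seq(1, by = 2, length.out = n_fix)]
  fix_off <- fix_on + fix_dur
  sacc_on <- if (n_sacc > 0) bounds[seq(2, by = 2, length.out = n_sacc)] else numeric(0)
  sacc_off <- sacc_on + sacc_dur

  m <- max(2L, round(D * rate))
  t <- (seq_len(m) - 1L) / rate
  seg <- findInterval(t, bounds, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(seg_dur))
  is_sacc_seg <- seg %% 2L == 0L
  fix_idx <- (seg + 1L) %/% 2L        # fixation index for fixation segments
  sacc_idx <- seg %/% 2L              # saccade index for saccade segments

  x <- numeric(m); y <- numeric(m)
  fi <- fix_idx[!is_sacc_seg]
  x[!is_sacc_seg] <- pts[fi, 1]
  y[!is_sacc_seg] <- pts[fi, 2]
  if (any(is_sacc_seg)) {
    sj <- sacc_idx[is_sacc_seg]
    u <- (t[is_sacc_seg] - sacc_on[sj]) / sacc_dur[sj]
    s <- saccade_profile(pmin(pmax(u, 0), 1))
    x[is_sacc_seg] <- pts[sj, 1] + (pts[sj + 1L, 1] - pts[sj, 1]) * s
    y[is_sacc_seg] <- pts[sj, 2] + (pts[sj + 1L, 2] - pts[sj, 2]) * s
  }
  x <- x + stats::rnorm(m, 0, config$tremor_sd)
  y <- y + stats::rnorm(m, 0, config$tremor_sd)
  x <- pmin(pmax(x, 0), config$screen_w - 1e-3)
  y <- pmin(pmax(y, 0), config$screen_h - 1e-3)

  # pupil: baseline + random-walk drift + one kernel per saccade
  pp <- config$pupil
  pupil <- pp$baseline_mm + cumsum(stats::rnorm(m, 0, pp$drift_sd / sqrt(rate)))
  boost <- rep(1, n_sacc)
  if (n_sacc > 0) {
    land_target <- aoi_seq[-1] == "target"
    boost[land_target & condition == "correct"] <-
      pp$target_correct_dilation_boost
    for (j in seq_len(n_sacc)) {
      idx <- which(t >= sacc_on[j] & t <= sacc_on[j] + 2)
      if (length(idx)) {
        pupil[idx] <- pupil[idx] +
          pupil_response_kernel(t[idx] - sacc_on[j], pp, boost = boost[j])
      }
    }
  }

  valid <- rep(TRUE, m)
  bl <- config$blink
  n_blink <- stats::rpois(1, bl$rate_hz * D)
  if (n_blink > 0) {
    # blinks happen during fixations (the lids are closed too briefly to
    # straddle a saccade), clipped to the fixation interval
    long_enough <- which(fix_dur >= 0.08)
    if (length(long_enough)) {
      for (j in seq_len(n_blink)) {
        fi <- long_enough[sample.int(length(long_enough), 1,
                                     prob = fix_dur[long_enough])]
        dur <- stats::runif(1, bl$dur_min_s, bl$dur_max_s)
        start <- stats::runif(1, fix_on[fi],
                              max(fix_on[fi], fix_off[fi] - dur))
        valid[t >= start & t < min(start + dur, fix_off[fi])] <- FALSE
      }
    }
  }
  if (stats::runif(1) < bl$dropout_prob) {
    frac <- stats::runif(1, bl$dropout_frac[1], bl$dropout_frac[2])
    start <- stats::runif(1, 0, D * (1 - frac))
    valid[t >= start & t < start + frac * D] <- FALSE
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_; pupil[!valid] <- NA_real_

  samples <- data.frame(t = t, x = x, y = y, pupil = pupil, valid = valid)
  gt <- list(
    condition = condition,
    fixations = data.frame(onset = fix_on, offset = fix_off,
                           aoi = aoi_seq, x = pts[, 1], y = pts[, 2],
                           stringsAsFactors = FALSE),
    saccades = if (n_sacc > 0) data.frame(
      onset = sacc_on, offset = sacc_off,
      from = aoi_seq[-n_fix], to = aoi_seq[-1],
      amplitude = amp, duration = sacc_dur,
      pupil_boost = boost, stringsAsFactors = FALSE
    ) else data.frame(onset = numeric(0), offset = numeric(0),
                      from = character(0), to = character(0),
                      amplitude = numeric(0), duration = numeric(0),
                      pupil_boost = numeric(0)),
    n_saccades = n_sacc
  )
  list(samples = samples, ground_truth = gt, duration = D, layout = layout)
}

#' Generate a synthetic cohort
#'
#' Simulates every subject of the configured cohort: 60 one-second exposure
#' trials followed by 90 retrieval trials (two blocks of 30 direct
#' associations, one block of 30 indirect associations). Per-trial
#' correctness is drawn from the subject's accuracy (direct accuracy from the
#' group block; indirect accuracy lower by `indirect_accuracy_offset`).
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `gaze_cohort`: a list of sessions (class
#'   `gaze_session`, each with `subject_id`, `group`, `sampling_rate`,
#'   `metadata`, and a list of trial records) plus a parallel list of
#'   per-subject ground truth.
#' @examples
#' coh <- generate_cohort(sim_config(n_hc = 1, n_tle = 1, seed = 3))
#' length(coh$sessions[[1]]$trials)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n_total <- config$n_hc + config$n_tle
    groups <- c(rep("HC", config$n_hc), rep("TLE", config$n_tle))
    sessions <- vector("list", n_total)
    ground_truth <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      grp <- groups[s]
      blk <- config$groups[[grp]]
      sid <- sprintf("S%02d", s)
      acc_direct <- rnorm_trunc(1, blk$direct_accuracy_mean, blk$accuracy_sd,
                                lower = 0.05, upper = 0.999)
      acc_indirect <- max(0.05, acc_direct - config$indirect_accuracy_offset)
      count_mult <- exp(stats::rnorm(1, -config$subject_sd^2 / 2,
                                     config$subject_sd))
      dur_mult <- exp(stats::rnorm(1, -config$subject_sd^2 / 2,
                                   config$subject_sd))
      acc_overall <- (2 * acc_direct + acc_indirect) / 3
      moca <- round(min(30, max(10, 30 * (0.35 + 0.65 * acc_overall) +
                                  stats::rnorm(1, 0, 1.5))))
      trials <- vector("list", 150L)
      gts <- vector("list", 150L)
      k <- 0L
      for (i in seq_len(60)) {
        k <- k + 1L
        tr <- generate_trial(list(phase = "exposure"), config)
        trials[[k]] <- make_trial_record(sid, k, "exposure", NA_character_,
                                         0L, "n.a.", grp, tr)
        gts[[k]] <- tr$ground_truth
      }
      sched <- data.frame(
        trial_type = rep(c("direct", "direct", "indirect"), each = 30),
        block = rep(1:3, each = 30)
      )
      for (i in seq_len(nrow(sched))) {
        k <- k + 1L
        acc <- if (sched$trial_type[i] == "direct") acc_direct else acc_indirect
        condition <- if (stats::runif(1) < acc) "correct" else "incorrect"
        tr <- generate_trial(
          list(phase = "retrieval", group = grp, condition = condition,
               count_mult = count_mult, dur_mult = dur_mult),
          config)
        trials[[k]] <- make_trial_record(sid, k, "retrieval",
                                         sched$trial_type[i], sched$block[i],
                                         condition, grp, tr)
        gts[[k]] <- tr$ground_truth
      }
      sessions[[s]] <- structure(
        list(subject_id = sid, group = grp,
             sampling_rate = config$sampling_rate,
             trials = trials,
             metadata = list(moca = moca, accuracy_direct = acc_direct,
                             accuracy_indirect = acc_indirect)),
        class = "gaze_session")
      names(gts) <- vapply(trials, function(tr) as.character(tr$trial_id), "")
      ground_truth[[s]] <- gts
    }
    names(sessions) <- vapply(sessions, `[[`, "", "subject_id")
    names(ground_truth) <- names(sessions)
    structure(list(sessions = sessions, ground_truth = ground_truth,
                   config = config),
              class = "gaze_cohort")
  })
}

make_trial_record <- function(sid, trial_id, phase, trial_type, block,
                              condition, group, tr) {
  structure(
    list(subject_id = sid, trial_id = trial_id, phase = phase,
         trial_type = trial_type, block = block, condition = condition,
         group = group, aoi = tr$layout, samples = tr$samples,
         response_time = if (phase == "retrieval") tr$duration else NA_real_),
    class = "gaze_trial")
}

#' @export
print.gaze_cohort <- function(x, ...) {
  groups <- vapply(x$sessions, `[[`, "", "group")
  cat(sprintf("Synthetic gaze cohort: %d subjects (%d HC, %d TLE), %g Hz\n",
              length(x$sessions), sum(groups == "HC"), sum(groups == "TLE"),
              x$config$sampling_rate))
  invisible(x)
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("Gaze session %s (%s): %d trials at %g Hz\n",
              x$subject_id, x$group, length(x$trials), x$sampling_rate))
  invisible(x)
}

#' Simulate a responder's choice on generated trials
#'
#' Maps a trial's ground truth to an explicit behavioural response.
#' `random` chooses target or lure uniformly (chance accuracy 50%),
#' `always_target` always picks the target, and `schedule_consistent`
#' reproduces the generated condition label (picking the target exactly on
#' trials generated as correct).
#'
#' @param ground_truth A trial ground-truth object from [generate_trial()].
#' @param policy One of `"random"`, `"always_target"`,
#'   `"schedule_consistent"`.
#' @param duration Trial duration in seconds (returned as the response time).
#' @return List with `choice` (`"target"` or `"lure"`) and
#'   `response_time` (s).
#' @export
simulate_responder <- function(ground_truth,
                               policy = c("random", "always_target",
                                          "schedule_consistent"),
                               duration = NA_real_) {
  policy <- match.arg(policy)
  choice <- switch(
    policy,
    random = sample(c("target", "lure"), 1),
    always_target = "target",
    schedule_consistent = if (identical(ground_truth$condition, "correct"))
      "target" else "lure"
  )
  list(choice = choice, response_time = duration)
}
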