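#' Detector parameters
#'
#' Defaults of the adaptive velocity-threshold detector family: threshold
#' multiplier `lambda = 6` on the median-based velocity SD, minimum saccade
#' duration of 3 samples, 20-ms merge interval for candidates separated by
#' sub-threshold dips, and 50-ms minimum fixation duration.
#'
#' @param lambda Threshold multiplier on the per-axis robust velocity SD.
#' @param min_saccade_samples Minimum supra-threshold run length (samples).
#' @param merge_interval Candidates closer than this (s) are merged.
#' @param min_fixation_duration Shortest inter-saccade interval (s) reported
#'   as a fixation.
#' @param sd_floor Lower bound (deg/s) on the robust SD, guarding degenerate
#'   traces.
#' @return A list of class `event_params`.
#' @export
event_params <- function(lambda = 6, min_saccade_samples = 3L,
                         merge_interval = 0.020,
                         min_fixation_duration = 0.050,
                         sd_floor = 0.1) {
  structure(list(lambda = lambda,
                 min_saccade_samples = as.integer(min_saccade_samples),
                 merge_interval = merge_interval,
                 min_fixation_duration = min_fixation_duration,
                 sd_floor = sd_floor),
            class = "event_params")
}

#' Gaze velocity from a sample stream
#'
#' Two-sided five-sample finite-difference velocity,
#' `v[i] = (p[i+1] + p[i+2] - p[i-1] - p[i-2]) / (6 dt)`, converted from
#' pixels to degrees of visual angle with the pinhole conversion of
#' `geometry`. The differencing kernel doubles as the smoothing step, so no
#' separate low-pass filter is applied. Samples whose stencil touches an
#' invalid sample get undefined (NA) velocity, as do the two samples at each
#' end.
#'
#' @param samples Data frame with `t`, `x`, `y`, `valid`.
#' @param geometry A [screen_geometry()].
#' @return Data frame of class `velocity_trace` with `t`, `vx`, `vy`,
#'   `speed` (deg/s).
#' @export
compute_velocity <- function(samples, geometry) {
  m <- nrow(samples)
  if (is.null(m) || m < 5L) {
    stopf("compute_velocity: need at least 5 samples (got %d)", m %||% 0L)
  }
  dt <- stats::median(diff(samples$t))
  x <- samples$x * geometry$deg_per_px_x
  y <- samples$y * geometry$deg_per_px_y
  x[!samples$valid] <- NA_real_
  y[!samples$valid] <- NA_real_
  vx <- rep(NA_real_, m)
  vy <- rep(NA_real_, m)
  i <- 3:(m - 2L)
  vx[i] <- (x[i + 1L] + x[i + 2L] - x[i - 1L] - x[i - 2L]) / (6 * dt)
  vy[i] <- (y[i + 1L] + y[i + 2L] - y[i - 1L] - y[i - 2L]) / (6 * dt)
  out <- data.frame(t = samples$t, vx = vx, vy = vy,
                    speed = sqrt(vx^2 + vy^2))
  class(out) <- c("velocity_trace", "data.frame")
  out
}

#' Detect saccades with an adaptive elliptic velocity threshold
#'
#' The per-axis threshold is `lambda` times the median-based robust SD
#' `sqrt(median(v^2) - median(v)^2)` of that trial's velocity. Samples with
#' `(vx/tx)^2 + (vy/ty)^2 > 1` are supra-threshold; runs of at least
#' `min_saccade_samples` are candidates; candidates separated by less than
#' `merge_interval` are merged; kinematics (amplitude in degrees, peak and
#' mean speed) are computed per event.
#'
#' @param vel A `velocity_trace` from [compute_velocity()].
#' @param samples The source samples (for positions at onset/offset).
#' @param geometry A [screen_geometry()].
#' @param params An [event_params()].
#' @return Data frame with one row per saccade: `onset`, `offset`,
#'   `x0, y0, x1, y1` (px), `amplitude` (deg), `peak_velocity`,
#'   `mean_velocity` (deg/s).
#' @export
detect_saccades <- function(vel, samples, geometry, params = event_params()) {
  defined <- is.finite(vel$vx) & is.finite(vel$vy)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      mean_velocity = numeric(0))
  if (!any(defined)) {
    warning("detect_saccades: all velocity samples undefined")
    return(empty)
  }
  robust_sd <- function(v) {
    v <- v[is.finite(v)]
    s2 <- stats::median(v^2) - stats::median(v)^2
    sqrt(max(s2, 0))
  }
  tx <- params$lambda * max(robust_sd(vel$vx), params$sd_floor)
  ty <- params$lambda * max(robust_sd(vel$vy), params$sd_floor)
  supra <- defined & ((vel$vx / tx)^2 + (vel$vy / ty)^2 > 1)
  supra[is.na(supra)] <- FALSE
  if (!any(supra)) return(empty)

  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= params$min_saccade_samples)
  if (!length(cand)) return(empty)
  on_idx <- starts[cand]
  off_idx <- ends[cand]

  # merge candidates separated by short sub-threshold dips
  if (length(cand) > 1L) {
    merged_on <- integer(0); merged_off <- integer(0)
    cur_on <- on_idx[1]; cur_off <- off_idx[1]
    for (j in 2:length(cand)) {
      gap <- vel$t[on_idx[j]] - vel$t[cur_off]
      if (gap < params$merge_interval) {
        cur_off <- off_idx[j]
      } else {
        merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
        cur_on <- on_idx[j]; cur_off <- off_idx[j]
      }
    }
    merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
    on_idx <- merged_on; off_idx <- merged_off
  }

  n <- length(on_idx)
  out <- data.frame(onset = vel$t[on_idx], offset = vel$t[off_idx],
                    x0 = samples$x[on_idx], y0 = samples$y[on_idx],
                    x1 = samples$x[off_idx], y1 = samples$y[off_idx],
                    amplitude = NA_real_, peak_velocity = NA_real_,
                    mean_velocity = NA_real_)
  for (j in seq_len(n)) {
    sp <- vel$speed[on_idx[j]:off_idx[j]]
    out$peak_velocity[j] <- max(sp, na.rm = TRUE)
    out$mean_velocity[j] <- mean(sp, na.rm = TRUE)
    out$amplitude[j] <- px_dist_deg(out$x0[j], out$y0[j],
                                    out$x1[j], out$y1[j], geometry)
  }
  out$amplitude[is.na(out$amplitude)] <- 0
  out
}

#' Derive fixations from the inter-saccade intervals
#'
#' Every interval between consecutive saccades (and between the trial edges
#' and the outermost saccades) at least `min_fixation_duration` long becomes
#' a fixation. The centroid is the mean of the valid samples in the
#' interval; its AOI label comes from centroid containment in `layout`
#' (`"off"` when no box contains it or no valid sample exists).
#'
#' @param samples Trial samples (`t`, `x`, `y`, `valid`).
#' @param saccades Saccade table from [detect_saccades()] (sorted,
#'   non-overlapping).
#' @param layout An [aoi_layout()].
#' @param params An [event_params()].
#' @return Data frame with `onset`, `offset`, `duration`, `x`, `y`
#'   (centroid px), `aoi_label`.
#' @export
detect_fixations <- function(samples, saccades, layout,
                             params = event_params()) {
  t0 <- samples$t[1]
  t1 <- samples$t[nrow(samples)]
  if (nrow(saccades) == 0L) {
    ivl_on <- t0; ivl_off <- t1
  } else {
    ivl_on <- c(t0, saccades$offset)
    ivl_off <- c(saccades$onset, t1)
  }
  keep <- (ivl_off - ivl_on) >= params$min_fixation_duration
  ivl_on <- ivl_on[keep]; ivl_off <- ivl_off[keep]
  n <- length(ivl_on)
  out <- data.frame(onset = ivl_on, offset = ivl_off,
                    duration = ivl_off - ivl_on,
                    x = NA_real_, y = NA_real_,
                    aoi_label = rep("off", n), stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    inw <- samples$t >= ivl_on[j] & samples$t <= ivl_off[j] & samples$valid
    if (any(inw)) {
      out$x[j] <- mean(samples$x[inw])
      out$y[j] <- mean(samples$y[inw])
      out$aoi_label[j] <- assign_aoi(out$x[j], out$y[j], layout)
    }
  }
  out
}

#' Detect all events of a trial
#'
#' Convenience wrapper running [compute_velocity()], [detect_saccades()] and
#' [detect_fixations()] on one (cleaned, non-excluded) trial.
#'
#' @param trial A `gaze_trial`.
#' @param geometry A [screen_geometry()].
#' @param params An [event_params()].
#' @return List with `saccades` and `fixations` tables.
#' @export
detect_events <- function(trial, geometry, params = event_params()) {
  vel <- compute_velocity(trial$samples, geometry)
  sac <- suppressWarnings(
    detect_saccades(vel, trial$samples, geometry, params))
  fix <- detect_fixations(trial$samples, sac, trial$aoi, params)
  list(saccades = sac, fixations = fix)
}

#' Write detected events as TSV
#'
#' One row per event with the documented columns
#' `subject_id,trial_id,kind,onset,offset,x0,y0,x1,y1,amplitude,
#' peak_velocity,aoi_label`.
#'
#' @param events_by_trial Named list (by trial id) of [detect_events()]
#'   results.
#' @param subject_id Subject identifier for the first column.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events_by_trial, subject_id, path) {
  rows <- lapply(names(events_by_trial), function(tid) {
    ev <- events_by_trial[[tid]]
    sac <- ev$saccades
    fix <- ev$fixations
    rbind(
      if (nrow(sac)) data.frame(
        subject_id = subject_id, trial_id = tid, kind = "saccade",
        onset = sac$onset, offset = sac$offset, x0 = sac$x0, y0 = sac$y0,
        x1 = sac$x1, y1 = sac$y1, amplitude = sac$amplitude,
        peak_velocity = sac$peak_velocity, aoi_label = NA_character_),
      if (nrow(fix)) data.frame(
        subject_id = subject_id, trial_id = tid, kind = "fixation",
        onset = fix$onset, offset = fix$offset, x0 = fix$x, y0 = fix$y,
        x1 = fix$x, y1 = fix$y, amplitude = NA_real_,
        peak_velocity = NA_real_, aoi_label = fix$aoi_label)
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
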