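#' Scanpath entropy of a trial
#'
#' Shannon entropy of the spatial occupancy distribution of gaze. Valid
#' samples are binned on a `grid` of cells covering the screen, the count
#' map is optionally smoothed with a truncated Gaussian kernel (in cell
#' units), normalised to a probability map, and
#' `H = -sum(p * log2(p))` is returned. The default 48 x 27 grid puts 40-px
#' cells on a 1920 x 1080 screen; absolute entropies depend on this choice,
#' so only orderings between conditions are comparable across setups.
#'
#' @param samples Trial samples (`x`, `y`, `valid`).
#' @param screen_w,screen_h Screen size in pixels.
#' @param grid Integer vector `c(nx, ny)` of cells.
#' @param smoothing_sd Gaussian smoothing SD in cells; 0 disables smoothing.
#' @return Entropy in bits, or `NA` (with attribute `reason`) when no valid
#'   sample exists.
#' @examples
#' sm <- data.frame(x = runif(100, 0, 1920), y = runif(100, 0, 1080),
#'                  valid = TRUE)
#' gaze_entropy(sm, 1920, 1080)
#' @export
gaze_entropy <- function(samples, screen_w, screen_h, grid = c(48L, 27L),
                         smoothing_sd = 1) {
  ok <- samples$valid & is.finite(samples$x) & is.finite(samples$y)
  if (!any(ok)) {
    return(structure(NA_real_, reason = "no valid samples"))
  }
  nx <- grid[1]; ny <- grid[2]
  ix <- pmin(nx - 1L, pmax(0L, floor(samples$x[ok] / (screen_w / nx))))
  iy <- pmin(ny - 1L, pmax(0L, floor(samples$y[ok] / (screen_h / ny))))
  counts <- matrix(0, ny, nx)
  tab <- table(iy * nx + ix)
  counts[as.integer(names(tab)) + 1L] <- as.numeric(tab)
  if (smoothing_sd > 0) {
    counts <- gauss_smooth2d(counts, smoothing_sd)
  }
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Separable 2-D Gaussian smoothing with zero padding (mass renormalised by
# the caller). Kernel truncated at 4 SD.
gauss_smooth2d <- function(mat, sd) {
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      j <- idx + o
      okk <- j >= 1 & j <= n
      B[cbind(idx[okk], j[okk])] <- B[cbind(idx[okk], j[okk])] +
        k[o + half + 1L]
    }
    B
  }
  band(nrow(mat)) %*% mat %*% band(ncol(mat))
}

#' Per-trial feature vector
#'
#' Computes the scanning features consumed by the statistics and decoding
#' stages. Dwell ratios come from raw valid samples (AOI membership over
#' valid trial time), not from fixation sums; fixation-based timing enters
#' through `mean_fixation_duration` and `time_to_first_target_fixation`. A
#' between-object saccade is one whose start and end positions fall in two
#' different stimulus AOIs. Pupil means per AOI use the `pupil_z` column
#' when the session has been z-scored.
#'
#' @param trial A cleaned, non-excluded `gaze_trial`.
#' @param saccades,fixations Event tables from [detect_events()].
#' @param window Optional cutoff `T` (s): features are computed on the
#'   sub-trial `[0, min(T, duration))` with events truncated at `T`.
#' @return One-row data frame with the feature columns and the trial's
#'   labels (`condition`, `group`, `trial_type`, `subject_id`, `trial_id`).
#' @export
trial_features <- function(trial, saccades, fixations, window = NULL) {
  if (isTRUE(trial$excluded)) {
    stopf("trial_features: trial %s was excluded (%s)",
          trial$trial_id, trial$exclusion_reason)
  }
  sm <- trial$samples
  duration <- sm$t[nrow(sm)] - sm$t[1] + stats::median(diff(sm$t))
  if (!is.null(window)) {
    stopifnot(window > 0)
    cut <- min(window, duration)
    keep <- sm$t < cut
    sm <- sm[keep, , drop = FALSE]
    saccades <- saccades[saccades$onset < cut, , drop = FALSE]
    saccades$offset <- pmin(saccades$offset, cut)
    fixations <- fixations[fixations$onset < cut, , drop = FALSE]
    fixations$offset <- pmin(fixations$offset, cut)
    fixations$duration <- fixations$offset - fixations$onset
    duration <- cut
  }
  ok <- sm$valid & is.finite(sm$x) & is.finite(sm$y)
  aoi <- assign_aoi(sm$x[ok], sm$y[ok], trial$aoi)
  n_ok <- sum(ok)
  dwell <- function(lab) if (n_ok) sum(aoi == lab) / n_ok else NA_real_
  tgt_fix <- fixations$onset[fixations$aoi_label == "target"]
  sac_aoi0 <- assign_aoi(saccades$x0, saccades$y0, trial$aoi)
  sac_aoi1 <- assign_aoi(saccades$x1, saccades$y1, trial$aoi)
  objs <- c("cue", "target", "lure")
  between <- sum(sac_aoi0 %in% objs & sac_aoi1 %in% objs &
                   sac_aoi0 != sac_aoi1)
  pupil_z <- if (!is.null(sm$pupil_z)) sm$pupil_z else rep(NA_real_, nrow(sm))
  pz <- function(lab) {
    v <- pupil_z[ok][aoi == lab]
    if (length(v) && any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_
  }
  data.frame(
    subject_id = trial$subject_id, trial_id = trial$trial_id,
    condition = trial$condition, group = trial$group,
    trial_type = trial$trial_type %||% NA_character_,
    trial_duration = duration,
    n_saccades = nrow(saccades),
    n_fixations = nrow(fixations),
    dwell_cue = dwell("cue"),
    dwell_target = dwell("target"),
    dwell_lure = dwell("lure"),
    time_to_first_target_fixation =
      if (length(tgt_fix)) min(tgt_fix) else NA_real_,
    n_between_object_saccades = between,
    entropy = as.numeric(gaze_entropy(sm, trial$aoi$screen_w,
                                      trial$aoi$screen_h)),
    mean_saccade_velocity = if (nrow(saccades))
      mean(saccades$mean_velocity, na.rm = TRUE) else NA_real_,
    peak_saccade_velocity = if (nrow(saccades))
      max(saccades$peak_velocity, na.rm = TRUE) else NA_real_,
    mean_fixation_duration = if (nrow(fixations))
      mean(fixations$duration) else NA_real_,
    pupil_mean_cue = pz("cue"),
    pupil_mean_target = pz("target"),
    pupil_mean_lure = pz("lure"),
    stringsAsFactors = FALSE
  )
}

#' Windowed feature vector
#'
#' [trial_features()] restricted to the first `T` seconds of the trial:
#' events are truncated at `T` and the `trial_duration` feature becomes
#' `min(T, duration)`. With `T` at or beyond the trial's duration the result
#' is identical to the full-trial features.
#'
#' @param trial,saccades,fixations As in [trial_features()].
#' @param T Window length in seconds (> 0).
#' @return One-row feature data frame.
#' @export
windowed_features <- function(trial, saccades, fixations, T) {
  trial_features(trial, saccades, fixations, window = T)
}

#' Time-binned dwell ratios
#'
#' Splits the trial into consecutive `bin_width` windows (default 250 ms;
#' the trailing partial bin keeps its own denominator) and returns, per bin,
#' the fraction of valid samples falling in each AOI. Off-AOI samples leave
#' the per-bin ratios summing below 1.
#'
#' @param trial A cleaned `gaze_trial`.
#' @param bin_width Bin width in seconds.
#' @return Data frame with `bin_start`, `bin_end`, `n_valid`, and one ratio
#'   column per stimulus AOI (`cue`, `target`, `lure`).
#' @export
binned_dwell_ratios <- function(trial, bin_width = 0.25) {
  sm <- trial$samples
  t0 <- sm$t[1]
  rel <- sm$t - t0
  dur <- rel[length(rel)] + stats::median(diff(sm$t))
  n_bins <- ceiling(dur / bin_width - 1e-9)
  bin <- pmin(n_bins, 1L + floor(rel / bin_width))
  ok <- sm$valid & is.finite(sm$x) & is.finite(sm$y)
  aoi <- rep("invalid", nrow(sm))
  aoi[ok] <- assign_aoi(sm$x[ok], sm$y[ok], trial$aoi)
  out <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_width,
                    bin_end = pmin(seq_len(n_bins) * bin_width, dur),
                    n_valid = 0L, cue = NA_real_, target = NA_real_,
                    lure = NA_real_)
  for (b in seq_len(n_bins)) {
    in_bin <- bin == b & ok
    nv <- sum(in_bin)
    out$n_valid[b] <- nv
    if (nv > 0) {
      for (lab in c("cue", "target", "lure")) {
        out[[lab]][b] <- sum(aoi[in_bin] == lab) / nv
      }
    }
  }
  out
}
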