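#' Z-score pupil diameter across a session
#'
#' Standardises pupil diameter over all valid samples of the whole session
#' (not per trial and with no per-epoch baseline subtraction, because the
#' pre-saccade pupil diameter is itself shaped by the preceding saccade's
#' response). Adds a `pupil_z` column to every trial's samples.
#'
#' @param session A `gaze_session`.
#' @return The session with `pupil_z` added; the session mean and SD are
#'   stored in `session$pupil_stats`.
#' @export
zscore_session <- function(session) {
  vals <- unlist(lapply(session$trials, function(tr) {
    tr$samples$pupil[tr$samples$valid]
  }))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) {
    stopf("zscore_session: need at least 2 valid pupil samples")
  }
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (sdv == 0) stopf("zscore_session: constant pupil (zero variance)")
  session$trials <- lapply(session$trials, function(tr) {
    tr$samples$pupil_z <- (tr$samples$pupil - mu) / sdv
    tr
  })
  session$pupil_stats <- c(mean = mu, sd = sdv)
  session
}

#' Extract event-locked pupil epochs
#'
#' One epoch per event whose window (default -0.25 to +1.25 s around the
#' event) lies entirely inside the trial. The z-scored pupil trace is
#' linearly interpolated onto a common 100-Hz grid; grid points inside
#' invalid spans stay undefined, and epochs with more than 30% undefined
#' points are dropped (mirroring the trial-level quality rule).
#'
#' @param trial A z-scored `gaze_trial`.
#' @param event_times Event times (s) within the trial, e.g. saccade onsets
#'   or fixation onsets.
#' @param labels Optional data frame of per-event labels (e.g. landing AOI)
#'   carried into the result.
#' @param window Length-2 window around the event (s).
#' @param epoch_rate Epoch grid rate (Hz).
#' @param max_undefined Drop threshold on the undefined fraction.
#' @return List with `epochs` (matrix, one row per kept epoch), `grid`
#'   (times relative to the event), `labels` (kept rows), `n_dropped`.
#' @export
extract_epochs <- function(trial, event_times, labels = NULL,
                           window = c(-0.25, 1.25), epoch_rate = 100,
                           max_undefined = 0.30) {
  sm <- trial$samples
  if (is.null(sm$pupil_z)) {
    stopf("extract_epochs: session must be z-scored first (no pupil_z)")
  }
  grid <- seq(window[1], window[2], by = 1 / epoch_rate)
  t0 <- sm$t[1]
  t1 <- sm$t[nrow(sm)]
  dt <- stats::median(diff(sm$t))
  ok <- sm$valid & is.finite(sm$pupil_z)
  keep_rows <- list()
  keep_lab <- integer(0)
  n_dropped <- 0L
  for (j in seq_along(event_times)) {
    e <- event_times[j]
    if (e + window[1] < t0 - 1e-9 || e + window[2] > t1 + 1e-9) {
      n_dropped <- n_dropped + 1L
      next
    }
    tt <- e + grid
    if (sum(ok) >= 2L) {
      z <- stats::approx(sm$t[ok], sm$pupil_z[ok], xout = tt, rule = 1)$y
    } else {
      z <- rep(NA_real_, length(tt))
    }
    # undefined where the nearest source sample is invalid
    near <- pmin(pmax(round((tt - t0) / dt) + 1L, 1L), nrow(sm))
    z[!ok[near]] <- NA_real_
    if (mean(!is.finite(z)) > max_undefined) {
      n_dropped <- n_dropped + 1L
      next
    }
    keep_rows[[length(keep_rows) + 1L]] <- z
    keep_lab <- c(keep_lab, j)
  }
  epochs <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    matrix(numeric(0), 0, length(grid))
  list(epochs = epochs, grid = grid,
       labels = if (!is.null(labels)) labels[keep_lab, , drop = FALSE] else
         NULL,
       n_dropped = n_dropped)
}

#' Average epochs by grouping labels
#'
#' Pointwise mean and standard error over epochs within each group. The mean
#' at a timepoint is reported only where at least half of the group's epochs
#' are defined there; groups with no epochs are omitted with a warning.
#'
#' @param epochs Matrix of epochs (rows) by timepoints (columns).
#' @param grid Time grid (s relative to the event).
#' @param groups Character/factor vector, one entry per epoch row.
#' @return Data frame with `group`, `t`, `mean`, `sem`, `n`.
#' @export
condition_average <- function(epochs, grid, groups) {
  stopifnot(nrow(epochs) == length(groups))
  out <- list()
  for (g in unique(groups)) {
    rows <- epochs[groups == g, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning(sprintf("condition_average: no epochs for group '%s'", g))
      next
    }
    n_def <- colSums(is.finite(rows))
    mu <- colMeans(rows, na.rm = TRUE)
    sdv <- apply(rows, 2, stats::sd, na.rm = TRUE)
    sem <- sdv / sqrt(pmax(n_def, 1))
    low <- n_def < nrow(rows) / 2
    mu[low] <- NA_real_
    sem[low] <- NA_real_
    out[[length(out) + 1L]] <- data.frame(group = g, t = grid, mean = mu,
                                          sem = sem, n = nrow(rows),
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Saccade-locked pupil epochs for a whole session
#'
#' Convenience wrapper: z-scores the session, detects events on the cleaned
#' retrieval trials, and extracts saccade-initiation-locked epochs labelled
#' by landing AOI and trial condition.
#'
#' @param session A `gaze_session`.
#' @param geometry A [screen_geometry()].
#' @param params An [event_params()].
#' @param window,epoch_rate See [extract_epochs()].
#' @return List with `epochs`, `grid`, `labels` (`aoi`, `condition`,
#'   `group`, `subject_id`), `n_dropped`.
#' @export
session_pupil_epochs <- function(session, geometry, params = event_params(),
                                 window = c(-0.25, 1.25), epoch_rate = 100) {
  session <- zscore_session(session)
  all_ep <- list(); all_lab <- list(); dropped <- 0L
  grid <- NULL
  for (tr in session$trials) {
    if (tr$phase != "retrieval") next
    tr <- validate_and_clean(tr, interpolate = TRUE)
    if (isTRUE(tr$excluded)) next
    ev <- detect_events(tr, geometry, params)
    sac <- ev$saccades
    if (nrow(sac) == 0L) next
    land <- assign_aoi(sac$x1, sac$y1, tr$aoi)
    lab <- data.frame(aoi = land, condition = tr$condition,
                      group = tr$group, subject_id = tr$subject_id,
                      stringsAsFactors = FALSE)
    ep <- extract_epochs(tr, sac$onset, labels = lab, window = window,
                         epoch_rate = epoch_rate)
    grid <- ep$grid
    dropped <- dropped + ep$n_dropped
    if (nrow(ep$epochs)) {
      all_ep[[length(all_ep) + 1L]] <- ep$epochs
      all_lab[[length(all_lab) + 1L]] <- ep$labels
    }
  }
  list(epochs = if (length(all_ep)) do.call(rbind, all_ep) else
         matrix(numeric(0), 0, length(grid %||% 0)),
       grid = grid,
       labels = if (length(all_lab)) do.call(rbind, all_lab) else NULL,
       n_dropped = dropped)
}
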