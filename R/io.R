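#' Write a gaze session to the documented CSV/TSV pair
#'
#' A session is stored as two files under `path`: `<subject>_samples.csv`
#' (columns `subject_id,trial_id,t,x,y,pupil,valid`) and
#' `<subject>_trials.tsv` (columns `subject_id,trial_id,phase,trial_type,
#' block,condition,group,aoi_json,response_time`). AOI layouts are embedded
#' as JSON rectangle maps. Floats use the decimal point; headers are
#' mandatory.
#'
#' @param session A `gaze_session`.
#' @param path Directory to write into (created if missing).
#' @return Invisibly, the two file paths.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  sid <- session$subject_id
  samples <- do.call(rbind, lapply(session$trials, function(tr) {
    cbind(data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id),
          tr$samples)
  }))
  trials <- do.call(rbind, lapply(session$trials, function(tr) {
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               phase = tr$phase,
               trial_type = ifelse(is.na(tr$trial_type), "", tr$trial_type),
               block = tr$block, condition = tr$condition, group = tr$group,
               aoi_json = as.character(aoi_to_json(tr$aoi)),
               response_time = tr$response_time,
               stringsAsFactors = FALSE)
  }))
  f_samples <- file.path(path, paste0(sid, "_samples.csv"))
  f_trials <- file.path(path, paste0(sid, "_trials.tsv"))
  utils::write.csv(format_float_df(samples), f_samples, row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.table(trials, f_trials, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(c(samples = f_samples, trials = f_trials))
}

# Format numeric columns with enough digits for a lossless round-trip.
format_float_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         formatC(df[[nm]], digits = 15, format = "g"))
    }
  }
  df
}

#' Read a gaze session from its CSV/TSV pair
#'
#' Inverse of [write_session()]: reconstructs the session field-for-field.
#' Mandatory columns are checked, per-trial timestamps must be strictly
#' increasing, phase labels must be `exposure` or `retrieval`, and a valid
#' sample must have a positive pupil diameter and on-screen coordinates;
#' violations raise a parse error naming the offending row.
#'
#' @param path Directory containing the pair, or the samples file itself.
#' @param subject_id Subject to read when `path` is a directory with several
#'   sessions; defaults to the only one present.
#' @return A `gaze_session`.
#' @export
read_session <- function(path, subject_id = NULL) {
  if (dir.exists(path)) {
    cand <- list.files(path, pattern = "_samples\\.csv$", full.names = TRUE)
    if (!is.null(subject_id)) {
      cand <- cand[basename(cand) == paste0(subject_id, "_samples.csv")]
    }
    if (length(cand) != 1L) {
      stopf("read_session: expected exactly one session in '%s' (found %d)",
            path, length(cand))
    }
    f_samples <- cand
  } else {
    f_samples <- path
  }
  f_trials <- sub("_samples\\.csv$", "_trials.tsv", f_samples)
  if (!file.exists(f_samples) || !file.exists(f_trials)) {
    stopf("read_session: missing samples or trials file for '%s'", f_samples)
  }
  samples <- utils::read.csv(f_samples, stringsAsFactors = FALSE)
  trials <- utils::read.table(f_trials, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, na.strings = "",
                              quote = "")
  need_s <- c("subject_id", "trial_id", "t", "x", "y", "pupil", "valid")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stopf("read_session: samples file missing column(s) %s",
                          paste(miss, collapse = ", "))
  need_t <- c("subject_id", "trial_id", "phase", "trial_type", "block",
              "condition", "group", "aoi_json", "response_time")
  miss <- setdiff(need_t, names(trials))
  if (length(miss)) stopf("read_session: trials file missing column(s) %s",
                          paste(miss, collapse = ", "))
  bad_phase <- which(!trials$phase %in% c("exposure", "retrieval"))
  if (length(bad_phase)) {
    stopf("read_session: unknown phase label '%s' (trials row %d)",
          trials$phase[bad_phase[1]], bad_phase[1])
  }
  samples$valid <- as.logical(samples$valid)
  bad_pupil <- which(samples$valid & (!is.finite(samples$pupil) |
                                        samples$pupil <= 0))
  if (length(bad_pupil)) {
    stopf("read_session: non-positive pupil on valid sample (samples row %d)",
          bad_pupil[1])
  }

  layouts <- lapply(trials$aoi_json, aoi_from_json)
  scr_w <- layouts[[1]]$screen_w
  bad_xy <- which(samples$valid &
                    (!is.finite(samples$x) | !is.finite(samples$y)))
  if (length(bad_xy)) {
    stopf("read_session: non-finite gaze on valid sample (samples row %d)",
          bad_xy[1])
  }

  split_idx <- split(seq_len(nrow(samples)), samples$trial_id)
  trial_list <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tid <- trials$trial_id[i]
    idx <- split_idx[[as.character(tid)]]
    if (is.null(idx)) stopf("read_session: trial %s has no samples", tid)
    sm <- samples[idx, c("t", "x", "y", "pupil", "valid")]
    if (any(diff(sm$t) <= 0)) {
      row <- idx[which(diff(sm$t) <= 0)[1] + 1L]
      stopf("read_session: non-monotone timestamps (samples row %d)", row)
    }
    rownames(sm) <- NULL
    trial_list[[i]] <- structure(
      list(subject_id = trials$subject_id[i], trial_id = tid,
           phase = trials$phase[i],
           trial_type = if (is.na(trials$trial_type[i]) ||
                            trials$trial_type[i] == "") NA_character_
                        else trials$trial_type[i],
           block = trials$block[i], condition = trials$condition[i],
           group = trials$group[i], aoi = layouts[[i]], samples = sm,
           response_time = trials$response_time[i]),
      class = "gaze_trial")
  }
  rate <- infer_sampling_rate(trial_list)
  structure(list(subject_id = trials$subject_id[1],
                 group = trials$group[1],
                 sampling_rate = rate, trials = trial_list,
                 metadata = list()),
            class = "gaze_session")
}

# Sampling rate from the median inter-sample interval of the session.
infer_sampling_rate <- function(trials) {
  dts <- unlist(lapply(trials, function(tr) diff(tr$samples$t)))
  1 / stats::median(dts)
}

#' Quality-control a trial: exclusion and gap interpolation
#'
#' A trial whose fraction of invalid raw samples exceeds
#' `max_invalid_fraction` (default 0.30) is marked excluded. Otherwise,
#' invalid gaps no longer than `max_gap` that are bracketed by valid samples
#' are linearly interpolated (gaze and pupil) and flagged in a new
#' `interpolated` column; longer gaps stay invalid. The exclusion decision is
#' computed on raw pre-interpolation counts, so it is invariant to sample
#' order.
#'
#' @param trial A `gaze_trial`.
#' @param max_invalid_fraction Exclusion threshold on the invalid fraction.
#' @param max_gap Longest gap (s) that may be filled by interpolation.
#' @param interpolate Whether to fill short gaps; off by default so that
#'   feature counting sees only measured samples (the pupil pathway turns it
#'   on).
#' @return The trial with an added `interpolated` sample column and
#'   attributes `excluded` (logical) and `exclusion_reason`.
#' @export
validate_and_clean <- function(trial, max_invalid_fraction = 0.30,
                               max_gap = 0.075, interpolate = FALSE) {
  sm <- trial$samples
  if (is.null(sm) || nrow(sm) == 0L) {
    trial$excluded <- TRUE
    trial$exclusion_reason <- "empty trial"
    return(trial)
  }
  frac_invalid <- mean(!sm$valid)
  sm$interpolated <- FALSE
  if (frac_invalid > max_invalid_fraction) {
    trial$excluded <- TRUE
    trial$exclusion_reason <- sprintf("invalid fraction %.2f > %.2f",
                                      frac_invalid, max_invalid_fraction)
    trial$samples <- sm
    return(trial)
  }
  if (interpolate && any(!sm$valid)) {
    r <- rle(sm$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1L || i1 == nrow(sm)) next          # edge gap: cannot bracket
      gap <- sm$t[i1 + 1L] - sm$t[i0 - 1L]
      if (gap > max_gap + 1e-9) next
      for (col in c("x", "y", "pupil")) {
        v0 <- sm[[col]][i0 - 1L]; v1 <- sm[[col]][i1 + 1L]
        w <- (sm$t[i0:i1] - sm$t[i0 - 1L]) / gap
        sm[[col]][i0:i1] <- v0 + w * (v1 - v0)
      }
      sm$valid[i0:i1] <- TRUE
      sm$interpolated[i0:i1] <- TRUE
    }
  }
  trial$excluded <- FALSE
  trial$exclusion_reason <- NA_character_
  trial$samples <- sm
  trial
}

#' Write a cohort to disk
#'
#' One session pair per subject plus a JSON ground-truth sidecar
#' (`<subject>_ground_truth.json`) when the cohort carries one.
#'
#' @param cohort A `gaze_cohort` from [generate_cohort()].
#' @param path Output directory.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (s in seq_along(cohort$sessions)) {
    ses <- cohort$sessions[[s]]
    write_session(ses, path)
    gt <- cohort$ground_truth[[s]]
    if (!is.null(gt)) {
      jsonlite::write_json(
        gt, file.path(path, paste0(ses$subject_id, "_ground_truth.json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  invisible(path)
}
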