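#' Simulation configuration for a synthetic HC/TLE cohort
#'
#' Bundles every parameter of the synthetic gaze/pupil generator: cohort
#' composition, screen geometry, per-group and per-condition behavioural
#' blocks, the post-saccadic pupil kernel, and blink/dropout rates. The
#' defaults encode the study conditions the package is designed around:
#' 14 healthy controls (HC) and 30 temporal-lobe-epilepsy (TLE) patients,
#' one-second exposure trials, open-ended cue-target-lure retrieval trials
#' whose durations average 3.83 s when correct and 4.79 s when incorrect,
#' 9.86 (HC) vs 13.38 (TLE) saccades per correct trial, and first fixations
#' on the target at 0.76 s (HC) vs 1.12 s (TLE).
#'
#' @param n_hc,n_tle Number of subjects per group.
#' @param sampling_rate Tracker rate in Hz; 90 or 120.
#' @param screen_w,screen_h Screen resolution in pixels.
#' @param screen_physical_w,screen_physical_h Physical screen size in cm.
#' @param viewing_distance Eye-to-screen distance in cm.
#' @param groups Named list (`HC`, `TLE`) of per-group blocks; see Details.
#' @param conditions Named list (`correct`, `incorrect`) of per-condition
#'   blocks; see Details.
#' @param indirect_accuracy_offset Indirect-trial accuracy is the subject's
#'   direct accuracy minus this offset.
#' @param subject_sd Log-scale SD of per-subject multipliers applied to
#'   saccade-count and duration means (between-subject heterogeneity).
#' @param tremor_sd Within-fixation per-sample positional noise (px).
#' @param min_refixation_dist Minimum displacement (px) imposed between
#'   consecutive fixations inside the same AOI, so every rendered saccade has
#'   a detectable amplitude.
#' @param pupil Pupil block: `baseline_mm`, `drift_sd` (mm per sqrt-second of
#'   random-walk drift), `constriction_amp` (mm), `constriction_latency_s`,
#'   `constriction_width_s`, `dilation_amp` (mm), `dilation_peak_s`,
#'   `target_correct_dilation_boost` (multiplier on the dilation lobe for
#'   saccades landing on the target in correct trials).
#' @param blink Blink/dropout block: `rate_hz`, `dur_min_s`, `dur_max_s`,
#'   plus `dropout_prob` and `dropout_frac` (range) for occasional tracker
#'   signal loss covering a large fraction of a trial.
#' @param exposure Exposure-phase block: `n_saccades_mean` (Poisson),
#'   `spatial_jitter_sd` (px; deliberately group-independent).
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @details
#' Each group block contains `direct_accuracy_mean`, `accuracy_sd`,
#' `saccade_count_mean_correct`, `saccade_count_mean_incorrect`,
#' `saccade_count_dispersion` (negative-binomial size),
#' `first_target_fixation_latency_mean`, `first_target_fixation_latency_sd`
#' (s), and `spatial_jitter_sd` (px; larger values disperse fixation landing
#' points and raise scanpath entropy). Each condition block contains
#' `trial_duration_mean`, `trial_duration_sd` (s) and
#' `target_dwell_bias_curve`, a matrix with one row per 250-ms bin and
#' columns `cue`, `target`, `lure` of nonnegative AOI-choice weights (the
#' last row extends to the end of the trial).
#'
#' @return A validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_hc = 2, n_tle = 2, seed = 7)
#' cfg$groups$TLE$saccade_count_mean_correct
#' @export
sim_config <- function(n_hc = 14, n_tle = 30,
                       sampling_rate = 120,
                       screen_w = 1920, screen_h = 1080,
                       screen_physical_w = 34.5, screen_physical_h = 19.4,
                       viewing_distance = 64,
                       groups = NULL,
                       conditions = NULL,
                       indirect_accuracy_offset = 0.15,
                       subject_sd = 0.08,
                       tremor_sd = 2,
                       min_refixation_dist = 200,
                       pupil = NULL,
                       blink = NULL,
                       exposure = NULL,
                       seed = 1L) {
  default_groups <- list(
    HC = list(direct_accuracy_mean = 0.90, accuracy_sd = 0.07,
              saccade_count_mean_correct = 9.86,
              saccade_count_mean_incorrect = 12.33,
              saccade_count_dispersion = 30,
              first_target_fixation_latency_mean = 0.76,
              first_target_fixation_latency_sd = 0.10,
              spatial_jitter_sd = 35),
    TLE = list(direct_accuracy_mean = 0.83, accuracy_sd = 0.11,
               saccade_count_mean_correct = 13.38,
               saccade_count_mean_incorrect = 16.73,
               saccade_count_dispersion = 30,
               first_target_fixation_latency_mean = 1.12,
               first_target_fixation_latency_sd = 0.30,
               spatial_jitter_sd = 60)
  )
  curve_correct <- rbind(
    c(cue = 0.70, target = 0.15, lure = 0.15),
    c(0.50, 0.25, 0.25),
    c(0.40, 0.30, 0.30),
    c(0.30, 0.45, 0.25),
    c(0.25, 0.50, 0.25)
  )
  curve_incorrect <- rbind(
    c(cue = 0.70, target = 0.15, lure = 0.15),
    c(0.50, 0.25, 0.25),
    c(0.40, 0.30, 0.30),
    c(0.30, 0.30, 0.40),
    c(0.25, 0.30, 0.45)
  )
  colnames(curve_correct) <- colnames(curve_incorrect) <-
    c("cue", "target", "lure")
  default_conditions <- list(
    correct = list(trial_duration_mean = 3.83, trial_duration_sd = 1.12,
                   target_dwell_bias_curve = curve_correct),
    incorrect = list(trial_duration_mean = 4.79, trial_duration_sd = 1.75,
                     target_dwell_bias_curve = curve_incorrect)
  )
  default_pupil <- list(baseline_mm = 3.5, drift_sd = 0.05,
                        constriction_amp = 0.04, constriction_latency_s = 0.25,
                        constriction_width_s = 0.09,
                        dilation_amp = 0.06, dilation_peak_s = 0.8,
                        target_correct_dilation_boost = 1.6)
  default_blink <- list(rate_hz = 0.1, dur_min_s = 0.1, dur_max_s = 0.3,
                        dropout_prob = 0.065, dropout_frac = c(0.3, 0.6))
  default_exposure <- list(n_saccades_mean = 2.5, spatial_jitter_sd = 45)

  cfg <- list(
    n_hc = n_hc, n_tle = n_tle, sampling_rate = sampling_rate,
    screen_w = screen_w, screen_h = screen_h,
    screen_physical_w = screen_physical_w,
    screen_physical_h = screen_physical_h,
    viewing_distance = viewing_distance,
    groups = modify_defaults(default_groups, groups),
    conditions = modify_defaults(default_conditions, conditions),
    indirect_accuracy_offset = indirect_accuracy_offset,
    subject_sd = subject_sd, tremor_sd = tremor_sd,
    min_refixation_dist = min_refixation_dist,
    pupil = modify_defaults(default_pupil, pupil),
    blink = modify_defaults(default_blink, blink),
    exposure = modify_defaults(default_exposure, exposure),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# Recursively overlay user-supplied entries on a default block list.
modify_defaults <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stopf("invalid sim_config: field '%s'", field)
  }
  chk(is.numeric(cfg$n_hc) && cfg$n_hc >= 0 && cfg$n_hc == round(cfg$n_hc), "n_hc")
  chk(is.numeric(cfg$n_tle) && cfg$n_tle >= 0 && cfg$n_tle == round(cfg$n_tle), "n_tle")
  chk(cfg$n_hc + cfg$n_tle >= 1, "n_hc/n_tle")
  chk(cfg$sampling_rate %in% c(90, 120), "sampling_rate")
  chk(cfg$screen_w > 0 && cfg$screen_h > 0, "screen_w/screen_h")
  chk(cfg$screen_physical_w > 0 && cfg$screen_physical_h > 0,
      "screen_physical_w/screen_physical_h")
  chk(cfg$viewing_distance > 0, "viewing_distance")
  chk(cfg$subject_sd >= 0, "subject_sd")
  chk(cfg$tremor_sd >= 0, "tremor_sd")
  chk(cfg$min_refixation_dist >= 0, "min_refixation_dist")
  for (g in c("HC", "TLE")) {
    blk <- cfg$groups[[g]]
    chk(!is.null(blk), paste0("groups$", g))
    acc <- blk$direct_accuracy_mean
    chk(is.numeric(acc) && acc > 0 && acc < 1,
        paste0("groups$", g, "$direct_accuracy_mean"))
    chk(blk$accuracy_sd >= 0, paste0("groups$", g, "$accuracy_sd"))
    chk(blk$saccade_count_mean_correct > 0,
        paste0("groups$", g, "$saccade_count_mean_correct"))
    chk(blk$saccade_count_mean_incorrect > 0,
        paste0("groups$", g, "$saccade_count_mean_incorrect"))
    chk(blk$saccade_count_dispersion > 0,
        paste0("groups$", g, "$saccade_count_dispersion"))
    chk(blk$first_target_fixation_latency_mean > 0,
        paste0("groups$", g, "$first_target_fixation_latency_mean"))
    chk(blk$first_target_fixation_latency_sd >= 0,
        paste0("groups$", g, "$first_target_fixation_latency_sd"))
    chk(blk$spatial_jitter_sd >= 0, paste0("groups$", g, "$spatial_jitter_sd"))
  }
  for (cd in c("correct", "incorrect")) {
    blk <- cfg$conditions[[cd]]
    chk(!is.null(blk), paste0("conditions$", cd))
    chk(blk$trial_duration_mean > 0,
        paste0("conditions$", cd, "$trial_duration_mean"))
    chk(blk$trial_duration_sd >= 0,
        paste0("conditions$", cd, "$trial_duration_sd"))
    crv <- blk$target_dwell_bias_curve
    chk(is.matrix(crv) && ncol(crv) == 3 && all(crv >= 0) &&
          all(rowSums(crv) > 0),
        paste0("conditions$", cd, "$target_dwell_bias_curve"))
  }
  chk(cfg$indirect_accuracy_offset >= 0 && cfg$indirect_accuracy_offset < 1,
      "indirect_accuracy_offset")
  pp <- cfg$pupil
  chk(pp$baseline_mm > 0, "pupil$baseline_mm")
  chk(pp$drift_sd >= 0, "pupil$drift_sd")
  chk(pp$constriction_amp >= 0, "pupil$constriction_amp")
  chk(pp$constriction_latency_s > 0, "pupil$constriction_latency_s")
  chk(pp$constriction_width_s > 0, "pupil$constriction_width_s")
  chk(pp$dilation_amp >= 0, "pupil$dilation_amp")
  chk(pp$dilation_peak_s > 0, "pupil$dilation_peak_s")
  chk(pp$target_correct_dilation_boost >= 0,
      "pupil$target_correct_dilation_boost")
  bl <- cfg$blink
  chk(bl$rate_hz >= 0, "blink$rate_hz")
  chk(bl$dur_min_s > 0 && bl$dur_max_s >= bl$dur_min_s,
      "blink$dur_min_s/dur_max_s")
  chk(bl$dropout_prob >= 0 && bl$dropout_prob <= 1, "blink$dropout_prob")
  chk(length(bl$dropout_frac) == 2 && all(bl$dropout_frac > 0) &&
        all(bl$dropout_frac < 1) && diff(bl$dropout_frac) >= 0,
      "blink$dropout_frac")
  chk(cfg$exposure$n_saccades_mean > 0, "exposure$n_saccades_mean")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d HC + %d TLE, %g Hz, screen %gx%g px\n",
              x$n_hc, x$n_tle, x$sampling_rate, x$screen_w, x$screen_h))
  cat(sprintf("  durations (s): correct %.2f, incorrect %.2f\n",
              x$conditions$correct$trial_duration_mean,
              x$conditions$incorrect$trial_duration_mean))
  cat(sprintf("  saccades/correct trial: HC %.2f, TLE %.2f\n",
              x$groups$HC$saccade_count_mean_correct,
              x$groups$TLE$saccade_count_mean_correct))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Geometry implied by a sim_config.
config_geometry <- function(cfg) {
  screen_geometry(cfg$screen_w, cfg$screen_h,
                  cfg$screen_physical_w, cfg$screen_physical_h,
                  cfg$viewing_distance)
}
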