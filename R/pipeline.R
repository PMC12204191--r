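#' Run configuration for the full analysis
#'
#' Bundles a simulation config (or an input directory of recorded
#' sessions), detector parameters, statistical settings and the decoding
#' protocol list. Every stochastic stage derives its own seed from the
#' global seed, so a run is reproducible from this object alone.
#'
#' @param sim A [sim_config()], or `NULL` when reading sessions from
#'   `input_dir`.
#' @param input_dir Directory of session files (used when `sim` is `NULL`).
#' @param detector An [event_params()].
#' @param max_invalid_fraction,max_gap Trial quality rules (see
#'   [validate_and_clean()]).
#' @param bin_width Dwell time-course bin width (s).
#' @param n_bins Number of dwell bins analysed (from trial start).
#' @param n_perm Permutations for cluster tests and feature importance.
#' @param protocols Decoding protocols to run (see [run_protocol()]).
#' @param windows Window lengths (s) for the windowed protocol.
#' @param pupil Whether to run the event-locked pupillometry stage.
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       detector = event_params(),
                       max_invalid_fraction = 0.30, max_gap = 0.075,
                       bin_width = 0.25, n_bins = 12L,
                       n_perm = 1000L,
                       protocols = c("accuracy", "duration_only",
                                     "diagnosis"),
                       windows = c(1, 3),
                       pupil = FALSE,
                       seed = 1L) {
  structure(list(sim = sim, input_dir = input_dir, detector = detector,
                 max_invalid_fraction = max_invalid_fraction,
                 max_gap = max_gap, bin_width = bin_width,
                 n_bins = as.integer(n_bins), n_perm = as.integer(n_perm),
                 protocols = protocols, windows = windows, pupil = pupil,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Clean, detect, and featurise a cohort
#'
#' Applies the trial-quality rules, the velocity-threshold event detector
#' and the feature extractor to every retrieval trial of every session;
#' pupil diameter is session z-scored first. The returned analysis object
#' retains the cleaned trials and event tables so that windowed feature
#' tables and pupil epochs can be derived without re-detection.
#'
#' @param cohort A `gaze_cohort` (or list of sessions under `$sessions`).
#' @param detector An [event_params()].
#' @param max_invalid_fraction Exclusion threshold.
#' @param geometry A [screen_geometry()]; derived from the cohort config if
#'   present.
#' @return Object of class `cohort_analysis`: `features` (one row per
#'   retained retrieval trial), `trials`, `events` (parallel lists),
#'   `exclusions` (count), `n_retrieval`, `geometry`, `detector`.
#' @export
analyze_cohort <- function(cohort, detector = event_params(),
                           max_invalid_fraction = 0.30, geometry = NULL) {
  sessions <- cohort$sessions %||% cohort
  if (is.null(geometry)) {
    geometry <- if (!is.null(cohort$config)) config_geometry(cohort$config)
    else screen_geometry()
  }
  feats <- list(); trials <- list(); events <- list()
  n_retrieval <- 0L; n_excluded <- 0L
  for (ses in sessions) {
    ses <- zscore_session(ses)
    moca <- ses$metadata$moca %||% NA_real_
    for (tr in ses$trials) {
      if (tr$phase != "retrieval") next
      n_retrieval <- n_retrieval + 1L
      tr <- validate_and_clean(tr, max_invalid_fraction = max_invalid_fraction)
      if (isTRUE(tr$excluded)) {
        n_excluded <- n_excluded + 1L
        next
      }
      ev <- detect_events(tr, geometry, detector)
      fr <- trial_features(tr, ev$saccades, ev$fixations)
      fr$moca <- moca
      key <- paste(tr$subject_id, tr$trial_id, sep = ":")
      feats[[key]] <- fr
      trials[[key]] <- tr
      events[[key]] <- ev
    }
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  structure(list(features = features, trials = trials, events = events,
                 exclusions = n_excluded, n_retrieval = n_retrieval,
                 geometry = geometry, detector = detector),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf(
    "Cohort analysis: %d retrieval trials, %d retained (%.1f%% excluded)\n",
    x$n_retrieval, nrow(x$features),
    100 * x$exclusions / max(1, x$n_retrieval)))
  invisible(x)
}

#' Windowed feature table for a cohort analysis
#'
#' Recomputes every retained trial's features on the first `window` seconds
#' (see [windowed_features()]); with `window = NULL` the stored full-trial
#' table is returned.
#'
#' @param analysis A `cohort_analysis`.
#' @param window Window length in seconds or `NULL`.
#' @return Feature data frame.
#' @export
feature_table <- function(analysis, window = NULL) {
  if (is.null(window)) return(analysis$features)
  rows <- lapply(names(analysis$trials), function(key) {
    tr <- analysis$trials[[key]]
    ev <- analysis$events[[key]]
    fr <- windowed_features(tr, ev$saccades, ev$fixations, T = window)
    fr$moca <- analysis$features$moca[match(key, paste(
      analysis$features$subject_id, analysis$features$trial_id, sep = ":"))]
    fr
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Subject-level means of every numeric feature, split by a label column.
subject_feature_means <- function(features, split_col) {
  num_cols <- names(features)[vapply(features, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("trial_id", "moca"))
  agg <- stats::aggregate(features[num_cols],
                          by = list(subject_id = features$subject_id,
                                    split = features[[split_col]]),
                          FUN = mean, na.rm = TRUE)
  agg
}

#' Subject-level group contrasts
#'
#' Rank-sum contrasts of subject-mean features: correct vs incorrect trials
#' (all retrieval trials), and HC vs TLE on correct trials only.
#'
#' @param features A cohort feature table.
#' @return List of two data frames (`condition`, `group`), one row per
#'   feature with the z statistic, p-value and group means.
#' @export
contrast_tables <- function(features) {
  run_contrasts <- function(df, split_col, lev_a, lev_b) {
    agg <- subject_feature_means(df, split_col)
    num_cols <- setdiff(names(agg), c("subject_id", "split"))
    rows <- lapply(num_cols, function(fc) {
      a <- agg[[fc]][agg$split == lev_a]
      b <- agg[[fc]][agg$split == lev_b]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      ts <- rank_sum_test(a, b)
      data.frame(feature = fc, mean_a = mean(a), mean_b = mean(b),
                 z = ts$statistic, p = ts$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "levels") <- c(lev_a, lev_b)
    out
  }
  list(
    condition = run_contrasts(
      features[features$condition %in% c("correct", "incorrect"), ],
      "condition", "correct", "incorrect"),
    group = run_contrasts(
      features[features$condition %in% "correct", ],
      "group", "HC", "TLE")
  )
}

#' Binned dwell-preference comparison with FDR correction
#'
#' Per 250-ms bin, the per-subject mean target-minus-lure dwell ratio is
#' compared between two trial sets (default: correct vs incorrect) with
#' rank-sum tests, corrected across bins by the Benjamini-Hochberg
#' procedure.
#'
#' @param analysis A `cohort_analysis`.
#' @param split_col Label column to contrast (`condition` or `group`).
#' @param lev_a,lev_b The two levels to compare.
#' @param bin_width Bin width (s).
#' @param n_bins Number of bins from trial start.
#' @param q FDR level.
#' @return Data frame, one row per bin: means per level, `z`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
binned_dwell_comparison <- function(analysis, split_col = "condition",
                                    lev_a = "correct", lev_b = "incorrect",
                                    bin_width = 0.25, n_bins = 12L, q = 0.05) {
  keys <- names(analysis$trials)
  feats <- analysis$features
  fkey <- paste(feats$subject_id, feats$trial_id, sep = ":")
  pref <- matrix(NA_real_, length(keys), n_bins)
  subj <- character(length(keys))
  lab <- character(length(keys))
  for (i in seq_along(keys)) {
    tr <- analysis$trials[[keys[i]]]
    bd <- binned_dwell_ratios(tr, bin_width)
    nb <- min(n_bins, nrow(bd))
    pref[i, seq_len(nb)] <- (bd$target - bd$lure)[seq_len(nb)]
    subj[i] <- tr$subject_id
    lab[i] <- feats[[split_col]][match(keys[i], fkey)]
  }
  rows <- lapply(seq_len(n_bins), function(b) {
    d <- data.frame(p = pref[, b], subj = subj, lab = lab)
    d <- d[is.finite(d$p) & d$lab %in% c(lev_a, lev_b), ]
    m <- stats::aggregate(p ~ subj + lab, data = d, FUN = mean)
    a <- m$p[m$lab == lev_a]; bb <- m$p[m$lab == lev_b]
    if (length(a) < 2 || length(bb) < 2) return(NULL)
    ts <- rank_sum_test(a, bb)
    data.frame(bin_start = (b - 1) * bin_width, bin_end = b * bin_width,
               mean_a = mean(a), mean_b = mean(bb), z = ts$statistic,
               p = ts$p)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_correct(out$p, q = q)
  out$p_adjusted <- fdr$adjusted
  out$significant <- fdr$reject
  attr(out, "levels") <- c(lev_a, lev_b)
  out
}

#' Event-locked pupil contrast with a cluster test
#'
#' Builds subject-level mean saccade-locked epochs for saccades landing on a
#' given AOI, split by trial condition, and runs the cluster-corrected
#' permutation test between the two sets of subject traces.
#'
#' @param sessions List of `gaze_session` objects.
#' @param geometry A [screen_geometry()].
#' @param aoi Landing AOI to analyse (default `"target"`).
#' @param n_perm,seed Passed to [cluster_permutation_test()].
#' @param detector An [event_params()].
#' @return List with `average` (condition-average traces),
#'   `cluster` (a `cluster_test`), and `grid`.
#' @export
pupil_condition_contrast <- function(sessions, geometry, aoi = "target",
                                     n_perm = 1000, seed = 1L,
                                     detector = event_params()) {
  subj_traces <- list()
  grid <- NULL
  for (ses in sessions) {
    ep <- session_pupil_epochs(ses, geometry, detector)
    grid <- ep$grid
    if (is.null(ep$labels) || nrow(ep$epochs) == 0L) next
    for (cond in c("correct", "incorrect")) {
      sel <- ep$labels$aoi == aoi & ep$labels$condition == cond
      if (sum(sel) >= 3L) {
        subj_traces[[length(subj_traces) + 1L]] <- list(
          cond = cond,
          trace = colMeans(ep$epochs[sel, , drop = FALSE], na.rm = TRUE))
      }
    }
  }
  conds <- vapply(subj_traces, `[[`, "", "cond")
  mat <- do.call(rbind, lapply(subj_traces, `[[`, "trace"))
  A <- mat[conds == "correct", , drop = FALSE]
  B <- mat[conds == "incorrect", , drop = FALSE]
  avg <- condition_average(mat, grid, conds)
  cl <- cluster_permutation_test(A, B, n_perm = n_perm, seed = seed,
                                 grid = grid)
  list(average = avg, cluster = cl, grid = grid)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> clean -> detect -> features -> stats
#' -> decode as one reproducible run: produces the feature table,
#' condition and group contrast tables, the binned dwell comparison with
#' FDR, optionally the event-locked pupil contrast with its cluster test,
#' and the configured decoding protocol reports. All stage seeds derive
#' from `config$seed`. With `out_dir` set, every table is written
#' (CSV/TSV/JSON) together with a manifest describing config and seeds; a
#' failing stage aborts with its name.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A report bundle (list) with elements `features`, `contrasts`,
#'   `binned_dwell`, `pupil` (or `NULL`), `decoding`, `exclusion_fraction`,
#'   `manifest`.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  cohort <- stage("simulate", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- derive_seed(config$seed, 1L)
      generate_cohort(sim)
    } else if (!is.null(config$input_dir)) {
      files <- list.files(config$input_dir, pattern = "_samples\\.csv$",
                          full.names = TRUE)
      sessions <- lapply(files, read_session)
      names(sessions) <- vapply(sessions, `[[`, "", "subject_id")
      list(sessions = sessions, config = NULL)
    } else stopf("run_config needs either sim or input_dir")
  })
  analysis <- stage("analyze", analyze_cohort(
    cohort, detector = config$detector,
    max_invalid_fraction = config$max_invalid_fraction))
  contrasts <- stage("stats", contrast_tables(analysis$features))
  binned <- stage("binned_dwell", binned_dwell_comparison(
    analysis, bin_width = config$bin_width, n_bins = config$n_bins))
  pupil <- if (isTRUE(config$pupil)) {
    stage("pupil", pupil_condition_contrast(
      cohort$sessions, analysis$geometry, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 2L), detector = config$detector))
  } else NULL
  decoding <- stage("decode", {
    out <- list()
    for (pr in config$protocols) {
      out[[pr]] <- run_protocol(analysis$features, pr,
                                seed = derive_seed(config$seed, 3L),
                                n_perm = min(config$n_perm, 100L))
    }
    if ("windowed" %in% config$protocols || length(config$windows)) {
      for (w in config$windows) {
        wt <- feature_table(analysis, window = w)
        out[[sprintf("windowed_%gs", w)]] <-
          run_protocol(wt, "windowed", window = w,
                       seed = derive_seed(config$seed, 3L), n_perm = 0)
      }
    }
    out
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("gazemem")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                       pupil = derive_seed(config$seed, 2L),
                       decode = derive_seed(config$seed, 3L)),
    n_subjects = length(cohort$sessions),
    n_retrieval_trials = analysis$n_retrieval,
    exclusion_fraction = analysis$exclusions / max(1, analysis$n_retrieval),
    protocols = names(decoding)
  )
  bundle <- list(features = analysis$features, contrasts = contrasts,
                 binned_dwell = binned, pupil = pupil, decoding = decoding,
                 exclusion_fraction = manifest$exclusion_fraction,
                 manifest = manifest, analysis = analysis)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(bundle$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(bundle$contrasts$condition,
                   file.path(out_dir, "contrast_condition.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$contrasts$group,
                   file.path(out_dir, "contrast_group.csv"),
                   row.names = FALSE)
  utils::write.table(bundle$binned_dwell,
                     file.path(out_dir, "binned_dwell.tsv"), sep = "\t",
                     row.names = FALSE)
  if (!is.null(bundle$pupil)) {
    utils::write.table(bundle$pupil$average,
                       file.path(out_dir, "pupil_average.tsv"), sep = "\t",
                       row.names = FALSE)
    writeLines(test_result_json(bundle$pupil$cluster),
               file.path(out_dir, "pupil_cluster.json"))
  }
  dec <- lapply(bundle$decoding, function(pr) {
    list(protocol = pr$protocol, restriction = pr$restriction,
         n_trials = pr$n_trials, folds = pr$decoding$k,
         auc = pr$decoding$auc, auc_per_fold = pr$decoding$auc_per_fold,
         importance = pr$importance, seed = pr$seed)
  })
  jsonlite::write_json(dec, file.path(out_dir, "decoding.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
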