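# Feature columns used by the decoders.
DECODING_FEATURES <- c(
  "trial_duration", "n_saccades", "n_fixations",
  "dwell_cue", "dwell_target", "dwell_lure",
  "time_to_first_target_fixation", "n_between_object_saccades", "entropy",
  "mean_saccade_velocity", "peak_saccade_velocity", "mean_fixation_duration",
  "pupil_mean_cue", "pupil_mean_target", "pupil_mean_lure"
)

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (Mann-Whitney form) with
#' midrank tie handling: the probability that a random positive scores above
#' a random negative, counting ties as one half.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Logical (or coercible) class labels; both classes required.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, TRUE, FALSE, TRUE))
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("auc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment. With `groups` given (e.g. subject ids), whole
# groups are dealt to folds, stratified by the group's label.
make_folds <- function(labels, k, groups = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  } else {
    gl <- tapply(labels, groups, function(v) v[1])
    gfold <- integer(length(gl))
    names(gfold) <- names(gl)
    for (cls in unique(gl)) {
      gs <- sample(names(gl)[gl == cls])
      gfold[gs] <- rep(seq_len(k), length.out = length(gs))
    }
    fold <- gfold[as.character(groups)]
  }
  as.integer(fold)
}

#' Cross-validated linear support-vector decoding
#'
#' Stratified k-fold cross-validation around a linear-kernel maximum-margin
#' classifier. Within each fold, missing feature values are imputed with
#' training-fold medians, each feature is z-scored with training-fold mean
#' and SD (which also transform the test fold), and per-class weights
#' inversely proportional to the training-class frequencies are applied.
#' Out-of-fold decision scores are pooled into a single cross-validated AUC
#' (every row is scored exactly once).
#'
#' @param X Numeric matrix or data frame of features (rows = trials).
#' @param y Binary labels (logical or coercible).
#' @param k Number of folds.
#' @param seed Seed controlling the fold draw.
#' @param groups Optional grouping vector (e.g. subject ids): whole groups
#'   stay in one fold, preventing identity leakage.
#' @param cost Soft-margin regularisation constant.
#' @param class_weight `"balanced"` (inverse-frequency class weights, the
#'   default) or `"none"`.
#' @return Object of class `decoder_cv`: pooled `auc` with a Hanley-McNeil
#'   normal `ci`, `auc_per_fold`, out-of-fold `scores`, `fold` assignment,
#'   frozen per-fold models (weights, offsets, scalers) for refit-free
#'   rescoring, and the `seed`.
#' @export
fit_decoder_cv <- function(X, y, k = 5, seed = 1L, groups = NULL, cost = 1,
                           class_weight = c("balanced", "none")) {
  class_weight <- match.arg(class_weight)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.logical(y)
  if (any(is.na(y))) stopf("fit_decoder_cv: labels must be complete")
  if (min(sum(y), sum(!y)) < k) {
    stopf("fit_decoder_cv: need at least k = %d rows per class", k)
  }
  n <- nrow(X)
  with_seed(seed, {
    fold <- make_folds(y, k, groups)
    for (retry in 1:5) {
      bad <- FALSE
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) bad <- TRUE
      }
      if (!bad) break
      fold <- make_folds(y, k, groups)    # re-stratify
    }
    if (bad) stopf("fit_decoder_cv: a class is absent from a training fold")

    scores <- rep(NA_real_, n)
    folds_info <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      med <- apply(X[tr, , drop = FALSE], 2, stats::median, na.rm = TRUE)
      med[!is.finite(med)] <- 0
      imp <- function(M) {
        for (j in seq_len(ncol(M))) M[!is.finite(M[, j]), j] <- med[j]
        M
      }
      Xtr <- imp(X[tr, , drop = FALSE])
      Xte <- imp(X[te, , drop = FALSE])
      ctr <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      Ztr <- sweep(sweep(Xtr, 2, ctr), 2, sdv, "/")
      Zte <- sweep(sweep(Xte, 2, ctr), 2, sdv, "/")
      yf <- factor(ifelse(y[tr], "pos", "neg"), levels = c("neg", "pos"))
      tab <- table(yf)
      wts <- if (class_weight == "balanced") {
        stats::setNames(as.numeric(length(tr) / (2 * tab)), names(tab))
      } else {
        stats::setNames(c(1, 1), names(tab))
      }
      m <- e1071::svm(Ztr, yf, kernel = "linear", cost = cost,
                      scale = FALSE, class.weights = wts)
      w <- as.numeric(t(m$coefs) %*% m$SV)
      dv_tr <- Ztr %*% w - m$rho
      # decision values are positive for the class named first in the
      # decision column; orient so higher = positive class
      first <- strsplit(colnames(attr(
        predict(m, Ztr[1, , drop = FALSE], decision.values = TRUE),
        "decision.values"))[1], "/")[[1]][1]
      orient <- if (first == "pos") 1 else -1
      scores[te] <- orient * (Zte %*% w - m$rho)
      folds_info[[f]] <- list(test = te, w = w, rho = m$rho,
                              orient = orient, center = ctr, scale = sdv,
                              medians = med)
    }
    auc_pool <- auc(scores, y)
    auc_fold <- vapply(seq_len(k), function(f) {
      te <- fold == f
      if (length(unique(y[te])) < 2L) NA_real_ else auc(scores[te], y[te])
    }, 0)
    n1 <- sum(y); n0 <- sum(!y)
    # Hanley-McNeil standard error of the AUC
    q1 <- auc_pool / (2 - auc_pool)
    q2 <- 2 * auc_pool^2 / (1 + auc_pool)
    se <- sqrt((auc_pool * (1 - auc_pool) +
                  (n1 - 1) * (q1 - auc_pool^2) +
                  (n0 - 1) * (q2 - auc_pool^2)) / (n1 * n0))
    structure(list(auc = auc_pool,
                   ci = c(max(0, auc_pool - 1.96 * se),
                          min(1, auc_pool + 1.96 * se)),
                   auc_per_fold = auc_fold, scores = scores, labels = y,
                   fold = fold, folds_info = folds_info, k = k,
                   cost = cost, seed = seed,
                   feature_names = colnames(X)),
              class = "decoder_cv")
  })
}

#' Score new rows with the frozen fold models
#'
#' Applies each fold's imputer, scaler and linear weights to the rows that
#' fold held out, producing decision scores on `newdata` without refitting.
#' With `newdata` equal to the training matrix this reproduces the
#' out-of-fold scores.
#'
#' @param object A `decoder_cv`.
#' @param newdata Matrix with the same columns (and row order) as the
#'   training matrix.
#' @param ... Unused.
#' @return Numeric decision scores (higher = positive class).
#' @export
predict.decoder_cv <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  scores <- rep(NA_real_, nrow(X))
  for (fi in object$folds_info) {
    M <- X[fi$test, , drop = FALSE]
    for (j in seq_len(ncol(M))) M[!is.finite(M[, j]), j] <- fi$medians[j]
    Z <- sweep(sweep(M, 2, fi$center), 2, fi$scale, "/")
    scores[fi$test] <- fi$orient * (Z %*% fi$w - fi$rho)
  }
  scores
}

#' @export
print.decoder_cv <- function(x, ...) {
  cat(sprintf(
    "Cross-validated linear SVC: pooled AUC %.3f (95%% CI %.3f-%.3f), %d folds\n",
    x$auc, x$ci[1], x$ci[2], x$k))
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$auc_per_fold),
                               collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.decoder_cv <- function(object, ...) {
  print(object)
  invisible(object)
}

# Refit-free rescoring of the frozen cross-validation with one feature
# column replaced. Scaling is linear, so the new pooled scores are the base
# scores plus w_j * (z_perm_j - z_base_j) per fold.
rescore_with_column <- function(fit, X, j, col_new) {
  scores <- fit$scores
  for (fi in fit$folds_info) {
    te <- fi$test
    v_new <- col_new[te]
    v_old <- X[te, j]
    v_new[!is.finite(v_new)] <- fi$medians[j]
    v_old[!is.finite(v_old)] <- fi$medians[j]
    dz <- (v_new - v_old) / fi$scale[j]
    scores[te] <- scores[te] + fi$orient * fi$w[j] * dz
  }
  scores
}

#' Permutation feature importance
#'
#' For each feature in turn, its column is permuted (keeping all other
#' features unchanged) `n_perm` times and the cross-validated AUC is
#' recomputed with frozen folds and refit-free scoring of the permuted test
#' folds. The importance score is the mean increase in model loss
#' `(1 - AUC)` over the permutations.
#'
#' @param fit A `decoder_cv` from [fit_decoder_cv()].
#' @param X The feature matrix the decoder was fitted on.
#' @param n_perm Number of permutations per feature.
#' @param seed Seed for the permutation draws.
#' @return Data frame of class `importance_table`: `feature`,
#'   `mean` and `sd` of the loss increase, `n_perm`; sorted by decreasing
#'   mean.
#' @export
permutation_importance <- function(fit, X, n_perm = 100, seed = 1L) {
  X <- as.matrix(X)
  base_loss <- 1 - fit$auc
  p <- ncol(X)
  with_seed(seed, {
    out <- data.frame(feature = colnames(X), mean = NA_real_, sd = NA_real_,
                      n_perm = n_perm, stringsAsFactors = FALSE)
    for (j in seq_len(p)) {
      dl <- vapply(seq_len(n_perm), function(r) {
        perm <- X[sample.int(nrow(X)), j]
        sc <- rescore_with_column(fit, X, j, perm)
        (1 - auc(sc, fit$labels)) - base_loss
      }, 0)
      out$mean[j] <- mean(dl)
      out$sd[j] <- stats::sd(dl)
    }
    out <- out[order(-out$mean), ]
    rownames(out) <- NULL
    class(out) <- c("importance_table", "data.frame")
    out
  })
}

#' Run a decoding protocol on a cohort feature table
#'
#' Applies the protocol's row restriction and feature selection, then
#' [fit_decoder_cv()] and [permutation_importance()]:
#' \describe{
#'   \item{accuracy}{correct vs incorrect, direct retrieval trials only
#'     (indirect trials differ systematically in duration), full feature
#'     set, stratified trial-wise folds.}
#'   \item{duration_only}{as `accuracy` but with `trial_duration` as the
#'     only feature.}
#'   \item{windowed}{as `accuracy` on a feature table computed from the
#'     first `window` seconds of each trial (pass the windowed table).}
#'   \item{diagnosis}{HC vs TLE on correct retrieval trials, subject-grouped
#'     folds by default to prevent identity leakage (set
#'     `subject_grouped = FALSE` for trial-wise folds).}
#'   \item{moca_split}{high vs low cognition score within the TLE group at
#'     the supplied `moca_threshold`; subject-grouped folds.}
#' }
#'
#' Missing first-target-fixation latencies are imputed with the trial
#' duration before fold-wise median imputation.
#'
#' @param features Cohort feature table (one row per retained retrieval
#'   trial) with label columns `condition`, `group`, `trial_type`,
#'   `subject_id`, and `moca` for the cognition split.
#' @param protocol Protocol name (see above).
#' @param window Window length (s), annotation only, when `features` is a
#'   windowed table.
#' @param moca_threshold Required for `moca_split`: scores strictly above it
#'   are the high class.
#' @param k,seed,cost Passed to [fit_decoder_cv()].
#' @param n_perm Permutations for the importance table (0 skips it).
#' @param subject_grouped Override the protocol's default fold grouping.
#' @return List of class `decoding_protocol`: `protocol`, `restriction`,
#'   `n_trials`, `decoding` (a `decoder_cv`), `importance`.
#' @export
run_protocol <- function(features,
                         protocol = c("accuracy", "duration_only",
                                      "windowed", "diagnosis", "moca_split"),
                         window = NULL, moca_threshold = NULL,
                         k = 5, seed = 1L, cost = 1, n_perm = 100,
                         subject_grouped = NULL) {
  protocol <- match.arg(protocol)
  df <- features
  feat_cols <- intersect(DECODING_FEATURES, names(df))
  grouped <- FALSE
  if (protocol %in% c("accuracy", "duration_only", "windowed")) {
    restriction <- "direct retrieval trials, correct vs incorrect"
    df <- df[df$trial_type %in% "direct" &
               df$condition %in% c("correct", "incorrect"), , drop = FALSE]
    label <- df$condition == "correct"
    if (protocol == "duration_only") feat_cols <- "trial_duration"
  } else if (protocol == "diagnosis") {
    restriction <- "correct retrieval trials, HC vs TLE"
    df <- df[df$condition %in% "correct", , drop = FALSE]
    label <- df$group == "TLE"
    grouped <- TRUE
  } else {
    if (is.null(moca_threshold)) {
      stopf("run_protocol: moca_split requires moca_threshold")
    }
    restriction <- sprintf("TLE correct trials, cognition score > %g",
                           moca_threshold)
    df <- df[df$group %in% "TLE" & df$condition %in% "correct", ,
             drop = FALSE]
    if (is.null(df$moca)) stopf("run_protocol: features lack a moca column")
    label <- df$moca > moca_threshold
    grouped <- TRUE
  }
  if (!is.null(subject_grouped)) grouped <- subject_grouped
  if (nrow(df) == 0L || length(unique(label)) < 2L) {
    stopf("run_protocol: restriction '%s' leaves a class empty", restriction)
  }
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  if ("time_to_first_target_fixation" %in% colnames(X)) {
    nas <- !is.finite(X[, "time_to_first_target_fixation"])
    X[nas, "time_to_first_target_fixation"] <- df$trial_duration[nas]
  }
  fit <- fit_decoder_cv(X, label, k = k, seed = seed,
                        groups = if (grouped) df$subject_id else NULL,
                        cost = cost)
  imp <- if (n_perm > 0) {
    permutation_importance(fit, X, n_perm = n_perm,
                           seed = derive_seed(seed, 101L))
  } else NULL
  structure(list(protocol = protocol, window = window,
                 restriction = restriction, n_trials = nrow(df),
                 decoding = fit, importance = imp, seed = seed),
            class = "decoding_protocol")
}

#' @export
print.decoding_protocol <- function(x, ...) {
  cat(sprintf("Decoding protocol '%s' (%s): %d trials\n",
              x$protocol, x$restriction, x$n_trials))
  print(x$decoding)
  if (!is.null(x$importance)) {
    cat("  top features by permutation importance:\n")
    top <- utils::head(x$importance, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-32s %+0.4f (sd %.4f)\n", top$feature[i],
                  top$mean[i], top$sd[i]))
    }
  }
  invisible(x)
}

#' ROC curve points
#'
#' Unique-threshold true/false positive rates of a score vector, suitable
#' for CSV export.
#'
#' @param scores,labels As in [auc()].
#' @return Data frame with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  thr <- unique(s)
  tpr <- vapply(thr, function(th) mean(s[l] >= th), 0)
  fpr <- vapply(thr, function(th) mean(s[!l] >= th), 0)
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}
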