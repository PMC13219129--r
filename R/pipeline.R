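#' Augmentation specification
#'
#' Each augmented sample re-estimates the FC features after (1) keeping a
#' random 70-80% of the timepoints (one draw shared by all networks — the
#' scan is one acquisition) and (2) keeping a random 70-80% of the voxels
#' within every ROI. Per optimization cycle, 10-500 augmented samples are
#' generated and 5-20% of them are reserved for validation termination.
#'
#' @param timepoint_fraction_range,voxel_fraction_range Subsampling
#'   fraction ranges in (0, 1\].
#' @param n_augmented_range Range of augmented sample counts per cycle.
#' @param val_fraction_range Validation split fraction range.
#' @return Object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(timepoint_fraction_range = c(0.70, 0.80),
                              voxel_fraction_range = c(0.70, 0.80),
                              n_augmented_range = c(10L, 500L),
                              val_fraction_range = c(0.05, 0.20)) {
  chk <- function(r, lo_ok) length(r) == 2L && r[1] <= r[2] && r[1] > 0
  if (!chk(timepoint_fraction_range) || !chk(voxel_fraction_range) ||
      !chk(val_fraction_range) || !chk(n_augmented_range) ||
      max(timepoint_fraction_range, voxel_fraction_range) > 1 ||
      max(val_fraction_range) >= 1) {
    stopf("degenerate augmentation spec ranges")
  }
  structure(list(timepoint_fraction_range = timepoint_fraction_range,
                 voxel_fraction_range = voxel_fraction_range,
                 n_augmented_range = as.integer(n_augmented_range),
                 val_fraction_range = val_fraction_range),
            class = "augmentation_spec")
}

#' Clip outcome outliers at a cap
#'
#' @param pfs_months Positive values (months).
#' @param cap Clipping cap, 24 months by default.
#' @return Elementwise `min(value, cap)`.
#' @export
clip_outcomes <- function(pfs_months, cap = 24) {
  if (any(pfs_months <= 0)) stopf("PFS values must be positive")
  pmin(pfs_months, cap)
}

# Subsample one subject's blocks: shared timepoint subset, per-network
# voxel subsets. Fraction 1 keeps everything.
subsample_blocks <- function(blocks, t_frac, v_frac) {
  Tn <- ncol(blocks[[1]])
  keep_t <- sort(sample.int(Tn, min(Tn, max(2L, ceiling(t_frac * Tn)))))
  lapply(blocks, function(b) {
    nv <- nrow(b)
    keep_v <- sort(sample.int(nv, min(nv, max(2L, ceiling(v_frac * nv)))))
    b[keep_v, keep_t, drop = FALSE]
  })
}

#' Generate one augmented FC feature vector from a subject
#'
#' Draws a timepoint fraction and a voxel fraction uniformly from the spec
#' ranges, subsamples without replacement, and recomputes the full FC
#' feature vector on the subsample. The original subject is untouched. If a
#' subsample leaves fewer than 2 timepoints or 2 voxels in any network it
#' is redrawn once, then the call errors.
#'
#' @param subject A [subject_timeseries()] object.
#' @param spec An [augmentation_spec()].
#' @param seed Integer seed.
#' @return Named numeric FC feature vector (length 120 for 15 networks).
#' @export
augment_subject <- function(subject, spec, seed = 1L) {
  stopifnot(inherits(subject, "subject_timeseries"),
            inherits(spec, "augmentation_spec"))
  with_seed(seed, {
    for (attempt in 1:2) {
      t_frac <- stats::runif(1, spec$timepoint_fraction_range[1],
                             spec$timepoint_fraction_range[2])
      v_frac <- stats::runif(1, spec$voxel_fraction_range[1],
                             spec$voxel_fraction_range[2])
      sub <- subsample_blocks(subject$blocks, t_frac, v_frac)
      ok <- ncol(sub[[1]]) >= 2L && all(vapply(sub, nrow, integer(1)) >= 2L)
      if (ok) return(fc_features_from_blocks(sub, impute = TRUE))
    }
    stopf("augmentation subsample too small for subject %s", subject$subject_id)
  })
}

#' Build one cycle's augmented training and validation sets
#'
#' Draws the number of augmented samples uniformly from the spec range,
#' generates each by [augment_subject()] from a uniformly chosen source
#' subject, assigns each row its source subject's (clipped) PFS, and
#' reserves a random 5-20% of the rows for validation termination. The
#' held-out LOOCV subject must not be among `subjects`.
#'
#' @param subjects List of [subject_timeseries()] (the fold's training
#'   subjects only).
#' @param pfs Clipped PFS for those subjects.
#' @param spec An [augmentation_spec()].
#' @param seed Integer seed.
#' @param features Optional column indices: restrict the returned matrices
#'   to these features (e.g. the fold's MRMR selection).
#' @param group_by_subject Draw the validation rows grouped by source
#'   subject (default). Validation rows then come from subjects that
#'   contribute no training rows (up to one boundary subject straddling
#'   the exact row count), so the validation loss measures generalization
#'   to unseen subjects rather than recall of jittered copies of the
#'   training rows.
#' @return List: `x_train`, `y_train`, `x_val`, `y_val`, `source`
#'   (source-subject index per augmented row, training first then
#'   validation), `n_augmented`.
#' @export
build_training_set <- function(subjects, pfs, spec, seed = 1L,
                               features = NULL, group_by_subject = TRUE) {
  stopifnot(length(subjects) == length(pfs), length(subjects) >= 1L)
  with_seed(seed, {
    n_aug <- if (spec$n_augmented_range[1] == spec$n_augmented_range[2]) {
      spec$n_augmented_range[1]
    } else {
      sample(spec$n_augmented_range[1]:spec$n_augmented_range[2], 1L)
    }
    src <- sample.int(length(subjects), n_aug, replace = TRUE)
    seeds <- sample.int(2147483646L, n_aug)
    X <- t(vapply(seq_len(n_aug), function(r) {
      augment_subject(subjects[[src[r]]], spec, seed = seeds[r])
    }, numeric(length(fc_feature_labels_for(subjects[[1]])))))
    if (!is.null(features)) X <- X[, features, drop = FALSE]
    y <- pfs[src]
    val_frac <- stats::runif(1, spec$val_fraction_range[1],
                             spec$val_fraction_range[2])
    n_val <- max(1L, round(val_frac * n_aug))
    n_val <- min(n_val, n_aug - 1L)
    if (group_by_subject) {
      # order rows by a random permutation of subjects and take the first
      # n_val rows: whole subjects go to validation, at most one straddles
      subj_order <- sample(length(subjects))
      row_order <- order(match(src, subj_order), sample.int(n_aug))
      val_idx <- sort(row_order[seq_len(n_val)])
    } else {
      val_idx <- sort(sample.int(n_aug, n_val))
    }
    tr_idx <- setdiff(seq_len(n_aug), val_idx)
    list(x_train = X[tr_idx, , drop = FALSE], y_train = y[tr_idx],
         x_val = X[val_idx, , drop = FALSE], y_val = y[val_idx],
         source = c(src[tr_idx], src[val_idx]), n_augmented = n_aug)
  })
}

fc_feature_labels_for <- function(subject) {
  fc_pair_labels(names(subject$blocks))$label
}

#' Prediction accuracy metrics
#'
#' RMSE, MAE, the coefficient of determination `R2 = 1 - SS_res / SS_tot`
#' (squared Pearson correlation is also reported as `r_squared_corr`), and
#' the p-value of the two-sided test of zero correlation between actual
#' and predicted.
#'
#' @param actual,predicted Numeric vectors (months).
#' @return List: `rmse`, `mae`, `r_squared`, `r_squared_corr`, `p_value`.
#' @export
compute_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2L)
  r <- predicted - actual
  ss_res <- sum(r^2)
  ss_tot <- sum((actual - mean(actual))^2)
  ct <- if (stats::sd(predicted) > 1e-12 && stats::sd(actual) > 1e-12) {
    stats::cor.test(actual, predicted)
  } else NULL
  list(rmse = sqrt(mean(r^2)), mae = mean(abs(r)),
       r_squared = 1 - ss_res / ss_tot,
       r_squared_corr = if (is.null(ct)) NA_real_ else unname(ct$estimate)^2,
       p_value = if (is.null(ct)) NA_real_ else ct$p.value)
}

cohort_fc_matrix <- function(cohort) {
  if (!is.null(cohort$fc)) return(cohort$fc)
  t(vapply(cohort$subjects, fc_feature_vector,
           numeric(length(fc_feature_labels_for(cohort$subjects[[1]])))))
}

#' Nested leave-one-out cross-validation of the ANN pipeline
#'
#' For each subject in turn: exclude it; rank features by MRMR on the
#' remaining subjects' full-data FC vectors; per optimization cycle, build
#' a fresh augmented training/validation set restricted to the fold's
#' selected features; run the hyperparameter search; predict the held-out
#' subject from its full-data FC restricted to the same features. All
#' randomness derives from `(seed, fold, cycle)`, so the held-out subject's
#' data and label never influence its fold's selection, augmentation or
#' splits.
#'
#' @param cohort An `fc_cohort` with raw time series.
#' @param widths,losses,restarts Hyperparameter grid (see
#'   [ann_hyperparameter_search()]).
#' @param k MRMR selection size (default 15).
#' @param aug_spec An [augmentation_spec()].
#' @param cap PFS clipping cap in months.
#' @param seed Master seed.
#' @param control [ann_config()] overrides.
#' @return Object of class `pfs_prediction`: `predicted`, `actual`
#'   (clipped PFS), `metrics`, `fold_features` (k x n matrix of selected
#'   indices), `fold_rankings`, `best_widths`, `search_n` per fold.
#' @export
loocv_run <- function(cohort, widths = c(5L, 10L), losses = "mse",
                      restarts = 5L, k = 15L, aug_spec = augmentation_spec(),
                      cap = 24, seed = 1L,
                      control = list(max_iter = 150L)) {
  stopifnot(inherits(cohort, "fc_cohort"), length(cohort$subjects) >= 3L)
  n <- length(cohort$subjects)
  fc <- cohort_fc_matrix(cohort)
  y <- clip_outcomes(cohort$pfs_months, cap)
  predicted <- numeric(n)
  fold_features <- matrix(NA_integer_, k, n)
  fold_rankings <- vector("list", n)
  best_widths <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    rk <- tryCatch(mrmr_rank(fc[tr, , drop = FALSE], y[tr], k = k),
                   error = function(e) stopf("fold %d: %s", i, conditionMessage(e)))
    sel <- rk$selected
    fold_rankings[[i]] <- rk
    fold_features[, i] <- sel
    fold_seed <- derive_seed(seed, 11L, i)
    data_fn <- function(s) {
      build_training_set(cohort$subjects[tr], y[tr], aug_spec, seed = s,
                         features = sel)
    }
    # retention scores a candidate on both training and validation
    # accuracy: mean of (a) its subject-grouped augmented-validation loss
    # and (b) its MSE on the fold's unaugmented training subjects at
    # full-data features; the held-out subject plays no part in either
    x_clean <- fc[tr, sel, drop = FALSE]
    y_clean <- y[tr]
    score_fn <- function(model) {
      0.5 * model$validation_loss +
        0.5 * mean((ann_predict(model, x_clean) - y_clean)^2)
    }
    sr <- tryCatch(
      ann_hyperparameter_search(data_fn, input_dim = k, widths = widths,
                                losses = losses, restarts = restarts,
                                seed = fold_seed, control = control,
                                score_fn = score_fn,
                                score_xy = list(x = x_clean, y = y_clean)),
      error = function(e) stopf("fold %d: %s", i, conditionMessage(e)))
    predicted[i] <- ann_predict(sr$best, fc[i, sel])
    best_widths[i] <- sr$best$config$width
  }
  structure(list(predicted = predicted, actual = y,
                 metrics = compute_metrics(y, predicted),
                 fold_features = fold_features,
                 fold_rankings = fold_rankings,
                 best_widths = best_widths, k = k, seed = seed),
            class = "pfs_prediction")
}

#' @export
print.pfs_prediction <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("pfs_prediction: n = %d | RMSE %.2f mo, MAE %.2f mo, R2 %.3f (p = %.2g)\n",
              length(x$predicted), m$rmse, m$mae, m$r_squared, m$p_value))
  invisible(x)
}

#' Linear LOOCV baseline on the same MRMR-selected features
#'
#' Ordinary least squares fit per fold on the fold's selected full-data
#' features (no augmentation), with the identical fold structure and
#' per-fold MRMR selection as [loocv_run()].
#'
#' @inheritParams loocv_run
#' @return A `pfs_prediction` object (with `fold_features`).
#' @export
linear_baseline <- function(cohort, k = 15L, cap = 24, seed = 1L) {
  stopifnot(inherits(cohort, "fc_cohort"), length(cohort$subjects) >= 3L)
  n <- length(cohort$subjects)
  fc <- cohort_fc_matrix(cohort)
  y <- clip_outcomes(cohort$pfs_months, cap)
  predicted <- numeric(n)
  fold_features <- matrix(NA_integer_, k, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- mrmr_rank(fc[tr, , drop = FALSE], y[tr], k = k)$selected
    fold_features[, i] <- sel
    Xtr <- cbind(1, fc[tr, sel, drop = FALSE])
    beta <- stats::lm.fit(Xtr, y[tr])$coefficients
    beta[is.na(beta)] <- 0
    predicted[i] <- sum(c(1, fc[i, sel]) * beta)
  }
  structure(list(predicted = predicted, actual = y,
                 metrics = compute_metrics(y, predicted),
                 fold_features = fold_features, k = k, seed = seed),
            class = "pfs_prediction")
}
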