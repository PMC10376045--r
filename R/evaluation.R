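# Accuracy metrics, threshold confusion analysis, leave-one-sheep-out
# evaluation, offset consistency and averaged deceleration profiles.

#' Regression accuracy metrics
#'
#' Mean absolute error (mmHg), mean absolute percentage error (%),
#' coefficient of determination R2 = 1 - SSres/SStot, and the 25/50/75th
#' percentiles of absolute error (same percentile convention as the
#' labelling: linear interpolation between order statistics).
#'
#' @param predictions,labels Equal-length numeric vectors, mmHg.
#' @return A `metric_set` list: `mae`, `mape`, `r2` (NA when the labels
#'   have zero variance), `abs_error_percentiles` (25/50/75), `n_records`.
#' @export
compute_metrics <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), length(labels) > 0)
  e <- predictions - labels
  sstot <- sum((labels - mean(labels))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(e^2) / sstot
  structure(list(
    mae = mean(abs(e)),
    mape = mape_loss(predictions, labels),
    r2 = r2,
    abs_error_percentiles = stats::quantile(abs(e), c(.25, .5, .75),
                                            type = 7),
    n_records = length(labels)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set: n=%d, MAE %.2f mmHg (25/50/75: %.2f/%.2f/%.2f), MAPE %.1f%%, R2 %s>\n",
    x$n_records, x$mae, x$abs_error_percentiles[1],
    x$abs_error_percentiles[2], x$abs_error_percentiles[3], x$mape,
    if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Confusion counts at a low-blood-pressure threshold
#'
#' Positive = measured FBP below the threshold; a prediction below the
#' threshold counts as an alarm. `confusion_counts()` builds the object
#' from raw counts; `threshold_confusion()` derives the counts from
#' prediction/label vectors.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @param threshold Threshold, mmHg.
#' @return A `confusion_counts` list with `sensitivity` = 100*tp/(tp+fn)
#'   and `specificity` = 100*tn/(tn+fp), in percent (NA when undefined).
#' @export
confusion_counts <- function(tp, tn, fp, fn, threshold = NA_real_) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(
    threshold = threshold, tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  ), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param predictions,labels Numeric vectors, mmHg.
#' @export
threshold_confusion <- function(predictions, labels, threshold) {
  stopifnot(length(predictions) == length(labels))
  pos <- labels < threshold
  alarm <- predictions < threshold
  confusion_counts(tp = sum(pos & alarm), tn = sum(!pos & !alarm),
                   fp = sum(!pos & alarm), fn = sum(pos & !alarm),
                   threshold = threshold)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion @ %s mmHg: tp %d tn %d fp %d fn %d | sens %.1f%% spec %.1f%%>\n",
    format(x$threshold), x$tp, x$tn, x$fp, x$fn, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Leave-one-sheep-out evaluation
#'
#' For each animal, a model is trained and validated on the segments of
#' all the other animals (sequential bin selection for the 5:1
#' train/validation split, low-FBP duplication in both) and then predicts
#' that animal's segments. Per-fold predictions are pooled and overall
#' metrics are computed on the concatenation (micro-averaging).
#'
#' @param dataset An unsplit `segment_dataset`.
#' @param mcfg A `model_config`.
#' @param tcfg A `train_config`.
#' @param acfg An `augmentation_config`.
#' @param bin_width FBP bin width for the split stratification, mmHg.
#' @param verbose Report folds as they complete.
#' @return List: `predictions` (data.frame with `sheep_id`,
#'   `occlusion_index`, `offset_s`, `label`, `prediction`), `metrics`
#'   (pooled `metric_set`), `fold_metrics` (per-animal `metric_set`s),
#'   `models` (per-animal trained models).
#' @export
run_loso <- function(dataset, mcfg = model_config(),
                     tcfg = train_config(),
                     acfg = augmentation_config(), bin_width = 5,
                     verbose = FALSE) {
  sheep <- unique(dataset$meta$sheep_id)
  if (length(sheep) < 2) stop("leave-one-out needs at least 2 animals")
  preds <- list()
  models <- list()
  fold_metrics <- list()
  for (sid in sheep) {
    ds <- make_splits(dataset,
                      split_config(test_sheep = sid,
                                   bin_width = bin_width,
                                   selection = "sequential",
                                   seed = tcfg$seed),
                      acfg)
    model <- tryCatch(
      train_on_dataset(ds, mcfg, tcfg),
      error = function(e) stop("training failed for fold '", sid, "': ",
                               conditionMessage(e)))
    te <- ds$meta$split == "test"
    p <- predict_min_fbp(model, ds$segments[te, , drop = FALSE])
    df <- ds$meta[te, c("sheep_id", "occlusion_index", "offset_s",
                        "label")]
    df$prediction <- p
    preds[[sid]] <- df
    models[[sid]] <- model
    fold_metrics[[sid]] <- compute_metrics(p, df$label)
    if (verbose) {
      message(sprintf("fold %s: n=%d, MAE %.2f mmHg", sid,
                      nrow(df), fold_metrics[[sid]]$mae))
    }
  }
  predictions <- do.call(rbind, c(preds, make.row.names = FALSE))
  list(predictions = predictions,
       metrics = compute_metrics(predictions$prediction,
                                 predictions$label),
       fold_metrics = fold_metrics,
       models = models)
}

#' Consistency of predictions across time-offset segments
#'
#' Absolute difference between the prediction for each time-offset segment
#' and the prediction for the located (offset 0) segment of the same
#' occlusion, summarised over all (occlusion, offset != 0) pairs.
#'
#' @param predictions Data.frame with `sheep_id`, `occlusion_index`,
#'   `offset_s`, `prediction` (e.g. from [run_loso()]).
#' @return List `mean`, `sd`, `max` (mmHg) and `n_occlusions`; occlusions
#'   without an offset-0 prediction are skipped with a warning.
#' @export
offset_consistency <- function(predictions) {
  key <- paste(predictions$sheep_id, predictions$occlusion_index,
               sep = ":")
  diffs <- numeric(0)
  skipped <- 0L
  for (grp in split(predictions, key)) {
    ref <- grp$prediction[grp$offset_s == 0]
    if (length(ref) != 1) {
      skipped <- skipped + 1L
      next
    }
    diffs <- c(diffs, abs(grp$prediction[grp$offset_s != 0] - ref))
  }
  if (skipped > 0) {
    warning(skipped, " occlusion(s) skipped (no located-segment ",
            "prediction)")
  }
  if (!length(diffs)) {
    return(list(mean = NA_real_, sd = NA_real_, max = NA_real_,
                n_occlusions = 0L))
  }
  list(mean = mean(diffs), sd = stats::sd(diffs), max = max(diffs),
       n_occlusions = length(unique(key)) - skipped)
}

#' Average deceleration profiles by value band
#'
#' Pointwise mean of normalised FHR segments grouped into bands of
#' predicted FBP, measured FBP or absolute prediction error — the
#' interpretation view relating deceleration shape (depth, duration,
#' overshoot) to blood pressure.
#'
#' @param segments Matrix of normalised segments (rows).
#' @param values One value per segment to band on (mmHg).
#' @param band_edges Increasing internal band edges; bands are
#'   (-Inf, e1], (e1, e2], ..., (ek, Inf).
#' @param grouping Label for the banding variable ("predicted",
#'   "measured" or "abs_error").
#' @return A `profile_summary`: `curves` (one mean curve per non-empty
#'   band), `n` per band, `band_labels`, `grouping`; empty bands are
#'   dropped and flagged in `empty_bands`.
#' @export
average_profiles <- function(segments, values,
                             band_edges = c(30, 40, 50),
                             grouping = c("measured", "predicted",
                                          "abs_error")) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(segments) == length(values),
            !is.unsorted(band_edges, strictly = TRUE))
  breaks <- c(-Inf, band_edges, Inf)
  band <- cut(values, breaks)
  labs <- levels(band)
  curves <- list()
  n <- integer(0)
  empty <- character(0)
  for (lv in labs) {
    rows <- which(band == lv)
    if (!length(rows)) {
      empty <- c(empty, lv)
      next
    }
    curves[[lv]] <- colMeans(segments[rows, , drop = FALSE])
    n[lv] <- length(rows)
  }
  structure(list(curves = curves, n = n, band_labels = labs,
                 empty_bands = empty, grouping = grouping),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("<profile_summary by %s: %d band(s), n = %s>\n",
              x$grouping, length(x$curves),
              paste(x$n, collapse = "/")))
  invisible(x)
}
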