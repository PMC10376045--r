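# Application of a trained model to human-style CTG traces: deceleration
# detection, 15-min-window baseline, prediction, outcome-group comparison
# and trend summaries.

#' Human CTG analysis configuration
#'
#' Segment handling is identical to the experimental extraction (same
#' 150 s segments, >50 s-missing exclusion, linear interpolation, same
#' 47.7 bpm normalisation divisor); only the baseline source differs: a
#' 15-min window centred on each deceleration.
#'
#' @param baseline_window Baseline window length, seconds (15 min).
#' @param decel_drop Minimum drop below baseline to call a deceleration,
#'   bpm.
#' @param decel_min_duration Minimum duration of the drop, seconds.
#' @param rolling_baseline_window Window of the rolling-median baseline
#'   used by the detector, seconds (odd).
#' @param ecfg An `extraction_config` (segment length/missing rule).
#' @param acfg An `augmentation_config` (normalisation divisor).
#' @return A `human_config` list. The detector thresholds follow common
#'   CTG practice (15 bpm for 15 s) and are exposed here because the
#'   clinical detector is conventional, not prescribed.
#' @export
human_config <- function(baseline_window = 900, decel_drop = 15,
                         decel_min_duration = 15,
                         rolling_baseline_window = 601,
                         ecfg = extraction_config(),
                         acfg = augmentation_config()) {
  stopifnot(baseline_window > 0, decel_drop > 0,
            decel_min_duration > 0,
            rolling_baseline_window %% 2 == 1)
  structure(list(baseline_window = baseline_window,
                 decel_drop = decel_drop,
                 decel_min_duration = decel_min_duration,
                 rolling_baseline_window = rolling_baseline_window,
                 ecfg = ecfg, acfg = acfg),
            class = "human_config")
}

#' Rolling-median FHR baseline
#'
#' Running median over a long window (gaps filled first), used as the
#' local reference level for deceleration detection.
#'
#' @param fhr 1 Hz FHR vector (NA = missing).
#' @param window Window length, samples (odd).
#' @return Baseline series, same length as `fhr`.
#' @export
rolling_baseline <- function(fhr, window = 601) {
  x <- fill_gaps(fhr)
  if (anyNA(x)) return(rep(NA_real_, length(fhr)))
  window <- min(window, length(x) - (1 - length(x) %% 2))
  stats::runmed(x, window, endrule = "median")
}

#' Detect decelerations in a CTG trace
#'
#' A deceleration is a run of at least `decel_min_duration` seconds during
#' which the FHR sits at least `decel_drop` bpm below the local baseline;
#' overlapping or touching runs merge. Missing samples are interpolated
#' first.
#'
#' @param fhr 1 Hz FHR vector.
#' @param baseline Baseline series (same length), e.g. from
#'   [rolling_baseline()].
#' @param cfg A `human_config`.
#' @return Data.frame with `start` and `end` times (0-based seconds,
#'   half-open); zero rows when no deceleration is found.
#' @export
detect_decelerations <- function(fhr, baseline = NULL,
                                 cfg = human_config()) {
  if (is.null(baseline)) {
    baseline <- rolling_baseline(fhr, cfg$rolling_baseline_window)
  }
  x <- fill_gaps(fhr)
  below <- !is.na(x) & (x <= baseline - cfg$decel_drop)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$decel_min_duration
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Baseline FHR around one deceleration
#'
#' Median of the non-missing, non-decelerative samples in a 15-min window
#' centred on the deceleration start (clipped at the trace edges).
#'
#' @param fhr 1 Hz FHR vector.
#' @param t Deceleration start time, seconds (0-based).
#' @param cfg A `human_config`.
#' @param decel_intervals Optional data.frame (`start`, `end`) of detected
#'   decelerations whose samples are excluded from the median.
#' @return Baseline FHR, bpm.
#' @export
compute_human_baseline <- function(fhr, t, cfg = human_config(),
                                   decel_intervals = NULL) {
  half <- cfg$baseline_window / 2
  lo <- max(0, t - half)
  hi <- min(length(fhr), t + half)
  idx <- (floor(lo) + 1):ceiling(hi)
  use <- !is.na(fhr[idx])
  if (!is.null(decel_intervals) && nrow(decel_intervals)) {
    times <- idx - 1
    for (r in seq_len(nrow(decel_intervals))) {
      use <- use & !(times >= decel_intervals$start[r] &
                       times < decel_intervals$end[r])
    }
  }
  if (!any(use)) {
    stop("baseline window around t=", t, " is fully missing")
  }
  stats::median(fhr[idx][use])
}

#' Predict minimum FBP for every deceleration of a human trace
#'
#' Per detected deceleration: slice the 150 s segment through the shared
#' extraction code path (missing-data exclusion, interpolation), subtract
#' the 15-min-window baseline, divide by the common 47.7 bpm and run the
#' model. Decelerations too close to the trace end for a full segment, or
#' failing the missing-data rule, are skipped.
#'
#' @param trace A human trace: list with `fhr` and `trace_id` (e.g. from
#'   [simulate_human_trace()]), or a bare numeric FHR vector.
#' @param model A trained `fbp_model`.
#' @param cfg A `human_config`.
#' @param starts Optional deceleration start times (seconds); detected
#'   automatically when NULL.
#' @return Data.frame of deceleration predictions: `trace_id`,
#'   `start_time`, `predicted_min_fbp` (mmHg), `n_prior_decels`,
#'   `time_to_end` (s); zero rows when the trace has no usable
#'   deceleration.
#' @export
predict_human <- function(trace, model, cfg = human_config(),
                          starts = NULL) {
  if (is.numeric(trace)) trace <- list(fhr = trace, trace_id = "ctg")
  fhr <- trace$fhr
  dec <- detect_decelerations(fhr, cfg = cfg)
  if (is.null(starts)) starts <- dec$start
  out <- data.frame(trace_id = character(0), start_time = numeric(0),
                    predicted_min_fbp = numeric(0),
                    n_prior_decels = integer(0),
                    time_to_end = numeric(0))
  if (!length(starts)) return(out)
  starts <- sort(starts)
  segs <- list()
  meta <- list()
  for (j in seq_along(starts)) {
    s <- starts[j]
    if (s + cfg$ecfg$segment_length > length(fhr)) next
    sl <- slice_segment(fhr, s, cfg$ecfg)
    if (sl$status != "kept") next
    bl <- tryCatch(
      compute_human_baseline(fhr, s, cfg, decel_intervals = dec),
      error = function(e) NA_real_)
    if (is.na(bl)) next
    segs[[length(segs) + 1]] <- normalise_segment(sl$segment, bl,
                                                  cfg$acfg)
    meta[[length(meta) + 1]] <- data.frame(
      trace_id = trace$trace_id, start_time = s,
      n_prior_decels = sum(starts < s),
      time_to_end = length(fhr) - s)
  }
  if (!length(segs)) return(out)
  m <- do.call(rbind, meta)
  m$predicted_min_fbp <- predict_min_fbp(model, do.call(rbind, segs))
  m[, c("trace_id", "start_time", "predicted_min_fbp",
        "n_prior_decels", "time_to_end")]
}

#' Compare predicted FBP between outcome groups
#'
#' Summary differences (mean and quartiles, group b minus group a) with
#' two-sided p-values from an independent two-sample Student's t-test and
#' a Mann-Whitney U-test.
#'
#' @param preds_a,preds_b Numeric vectors of predicted minimum FBP, mmHg
#'   (e.g. non-severe vs severe outcome groups).
#' @return List: `mean_difference`, `quartile_differences` (25/50/75),
#'   `t_test_p`, `mann_whitney_p`, `degenerate` (TRUE when either sample
#'   is constant, in which case the p-values are NA).
#' @export
compare_groups <- function(preds_a, preds_b) {
  stopifnot(length(preds_a) > 0, length(preds_b) > 0)
  degenerate <- stats::sd(preds_a) == 0 && stats::sd(preds_b) == 0
  qd <- stats::quantile(preds_b, c(.25, .5, .75), type = 7) -
    stats::quantile(preds_a, c(.25, .5, .75), type = 7)
  list(
    mean_difference = mean(preds_b) - mean(preds_a),
    quartile_differences = qd,
    t_test_p = if (degenerate) NA_real_ else
      stats::t.test(preds_b, preds_a)$p.value,
    mann_whitney_p = if (degenerate) NA_real_ else
      stats::wilcox.test(preds_b, preds_a, exact = FALSE)$p.value,
    degenerate = degenerate
  )
}

#' Trend of predictions against a covariate
#'
#' Mean predicted FBP binned by the number of prior decelerations or the
#' time to the end of the trace. Monotonicity is reported, not enforced.
#'
#' @param preds Data.frame from [predict_human()] (rows may pool traces).
#' @param covariate "n_prior_decels" or "time_to_end".
#' @param bins Number of equal-width covariate bins.
#' @return Data.frame with `bin_mid`, `mean_prediction`, `n` (empty bins
#'   omitted).
#' @export
trend_summary <- function(preds, covariate = c("n_prior_decels",
                                               "time_to_end"),
                          bins = 10) {
  covariate <- match.arg(covariate)
  x <- preds[[covariate]]
  stopifnot(!anyNA(x))
  if (length(unique(x)) == 1) {
    return(data.frame(bin_mid = unique(x),
                      mean_prediction = mean(preds$predicted_min_fbp),
                      n = length(x)))
  }
  edges <- seq(min(x), max(x), length.out = bins + 1)
  b <- cut(x, edges, include.lowest = TRUE)
  agg <- tapply(preds$predicted_min_fbp, b, mean)
  cnt <- tapply(preds$predicted_min_fbp, b, length)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  keep <- !is.na(agg)
  data.frame(bin_mid = mids[keep], mean_prediction = as.numeric(agg[keep]),
             n = as.integer(cnt[keep]))
}
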