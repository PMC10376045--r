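# Occlusion location, 150 s segment slicing, percentile labelling and
# discard rules. Time convention throughout: 0-based seconds, half-open
# windows; the sample at time t is element t+1 of the 1 Hz vector.

#' Extraction configuration
#'
#' Rules for slicing FHR segments and labelling occlusions with their
#' minimum FBP. A segment is excluded when more than `max_missing` seconds
#' are missing; remaining gaps are linearly interpolated. The label is the
#' `label_percentile`th percentile of FBP over the last `label_tail`
#' seconds of the segment (skipping the first 15 s so a low value cannot
#' leak in from the previous occlusion); if that falls below
#' `fallback_trigger` the label is recomputed as the
#' `fallback_percentile`th percentile during the occlusion itself. Records
#' are discarded when the label jumps by more than `max_consecutive_change`
#' between consecutive kept occlusions, or lands outside
#' `[fbp_lower_bound, fbp_upper_bound]`.
#'
#' @param segment_length Segment length, seconds.
#' @param max_missing Maximum tolerated missing data per segment, seconds.
#' @param label_tail Tail window used for the primary label, seconds.
#' @param label_percentile Primary label percentile (of the tail window).
#' @param fallback_percentile Fallback percentile (over the occlusion).
#' @param fallback_trigger Primary label below this (mmHg) triggers the
#'   fallback.
#' @param max_consecutive_change Maximum allowed change in labelled FBP
#'   between consecutive occlusions, mmHg.
#' @param fbp_lower_bound,fbp_upper_bound Plausible label range, mmHg.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(segment_length = 150, max_missing = 50,
                              label_tail = 135, label_percentile = 3,
                              fallback_percentile = 20,
                              fallback_trigger = 10,
                              max_consecutive_change = 18,
                              fbp_lower_bound = 10, fbp_upper_bound = 80) {
  cfg <- as.list(environment())
  stopifnot(cfg$label_tail <= cfg$segment_length,
            cfg$fallback_trigger == cfg$fbp_lower_bound,
            all(unlist(cfg) > 0))
  class(cfg) <- "extraction_config"
  cfg
}

#' Locate occlusion start times
#'
#' Arithmetic sequence `first_start + k * spacing` for k = 0, 1, ... while a
#' full segment still fits in the trace.
#'
#' @param first_start Manually located start of the first occlusion, s.
#' @param spacing Occlusion spacing, s.
#' @param trace_length Trace length, s.
#' @param segment_length Segment length that must fit, s.
#' @return Numeric vector of start times (possibly empty).
#' @export
locate_occlusion_starts <- function(first_start, spacing, trace_length,
                                    segment_length = 150) {
  stopifnot(first_start >= 0, spacing > 0)
  k_max <- floor((trace_length - segment_length - first_start) / spacing)
  if (k_max < 0) return(numeric(0))
  first_start + spacing * (0:k_max)
}

# Linear interpolation of interior gaps, nearest-value extension at edges.
fill_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (!length(ok)) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

#' Slice one 150 s FHR segment
#'
#' @param fhr 1 Hz FHR vector (NA = missing).
#' @param start Segment start time, seconds (0-based).
#' @param cfg An `extraction_config`.
#' @return List with `status` ("kept" or "excluded_missing") and `segment`
#'   (gap-free numeric vector of length `segment_length`, or NULL).
#' @export
slice_segment <- function(fhr, start, cfg = extraction_config()) {
  idx <- (start + 1):(start + cfg$segment_length)
  if (start < 0 || max(idx) > length(fhr)) {
    stop("segment [", start, ", ", start + cfg$segment_length,
         ") out of trace range")
  }
  seg <- fhr[idx]
  if (sum(is.na(seg)) > cfg$max_missing) {
    return(list(status = "excluded_missing", segment = NULL))
  }
  list(status = "kept", segment = fill_gaps(seg))
}

#' Label an occlusion with its minimum FBP
#'
#' Primary label: 3rd percentile of FBP over the last 135 s of the segment.
#' If that is below 10 mmHg (abnormally low, usually noise) the label is
#' recomputed as the 20th percentile of FBP during the occlusion window.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); missing FBP samples are dropped before the
#' percentile is taken.
#'
#' @param fbp 1 Hz FBP vector (NA = missing).
#' @param start Segment/occlusion start time, seconds.
#' @param occlusion_length Occlusion duration, seconds.
#' @param cfg An `extraction_config`.
#' @return List `min_fbp` (mmHg, NA if the window is fully missing) and
#'   `label_method` ("primary" or "fallback").
#' @export
compute_min_fbp <- function(fbp, start, occlusion_length,
                            cfg = extraction_config()) {
  stopifnot(start + cfg$segment_length <= length(fbp))
  tail_idx <- (start + cfg$segment_length - cfg$label_tail + 1):
    (start + cfg$segment_length)
  tail_vals <- fbp[tail_idx]
  tail_vals <- tail_vals[!is.na(tail_vals)]
  if (!length(tail_vals)) {
    return(list(min_fbp = NA_real_, label_method = NA_character_))
  }
  primary <- unname(stats::quantile(tail_vals, cfg$label_percentile / 100,
                                    type = 7))
  if (primary >= cfg$fallback_trigger) {
    return(list(min_fbp = primary, label_method = "primary"))
  }
  occ_vals <- fbp[(start + 1):(start + occlusion_length)]
  occ_vals <- occ_vals[!is.na(occ_vals)]
  if (!length(occ_vals)) {
    return(list(min_fbp = NA_real_, label_method = NA_character_))
  }
  list(min_fbp = unname(stats::quantile(
         occ_vals, cfg$fallback_percentile / 100, type = 7)),
       label_method = "fallback")
}

#' Apply the discard rules to an ordered record table
#'
#' Working through a sheep's kept records in occlusion order: a record
#' whose label differs from the previous kept record's label by more than
#' `max_consecutive_change` mmHg becomes `discarded_jump`; a label below
#' `fbp_lower_bound` (even after fallback relabelling) or above
#' `fbp_upper_bound` becomes `discarded_range`.
#'
#' @param records Data.frame with columns `occlusion_index`, `min_fbp`,
#'   `status` (sorted by `occlusion_index` within one sheep).
#' @param cfg An `extraction_config`.
#' @return The records with updated `status`.
#' @export
apply_discard_rules <- function(records, cfg = extraction_config()) {
  stopifnot(!is.unsorted(records$occlusion_index))
  prev_kept <- NA_real_
  for (i in seq_len(nrow(records))) {
    if (records$status[i] != "kept") next
    v <- records$min_fbp[i]
    if (is.na(v)) {
      records$status[i] <- "excluded_missing"
    } else if (v < cfg$fbp_lower_bound || v > cfg$fbp_upper_bound) {
      records$status[i] <- "discarded_range"
    } else if (!is.na(prev_kept) &&
               abs(v - prev_kept) > cfg$max_consecutive_change) {
      records$status[i] <- "discarded_jump"
    } else {
      prev_kept <- v
    }
  }
  records
}

#' Extract and label every occlusion of one trace
#'
#' Runs occlusion location, segment slicing (with the missing-data
#' exclusion and gap interpolation), percentile labelling and the discard
#' rules for one experiment trace.
#'
#' @param trace An `experiment_trace` with FBP.
#' @param cfg An `extraction_config`.
#' @return List with `records` (data.frame: `sheep_id`, `occlusion_index`,
#'   `start_time`, `min_fbp`, `label_method`, `status`) and `segments`
#'   (matrix, one row per record; NA rows for excluded records).
#' @export
extract_occlusions <- function(trace, cfg = extraction_config()) {
  stopifnot(inherits(trace, "experiment_trace"), !is.null(trace$fbp),
            !is.null(trace$group))
  starts <- locate_occlusion_starts(trace$first_occlusion_start,
                                    trace$group$occlusion_spacing,
                                    length(trace$fhr), cfg$segment_length)
  n <- length(starts)
  segs <- matrix(NA_real_, n, cfg$segment_length)
  records <- data.frame(
    sheep_id = rep(trace$sheep_id, n),
    occlusion_index = seq_len(n),
    start_time = starts,
    min_fbp = NA_real_,
    label_method = NA_character_,
    status = rep("kept", n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    sl <- slice_segment(trace$fhr, starts[i], cfg)
    if (sl$status != "kept") {
      records$status[i] <- sl$status
      next
    }
    segs[i, ] <- sl$segment
    lab <- compute_min_fbp(trace$fbp, starts[i],
                           trace$group$occlusion_length, cfg)
    records$min_fbp[i] <- lab$min_fbp
    records$label_method[i] <- lab$label_method
  }
  records <- apply_discard_rules(records, cfg)
  list(records = records, segments = segs)
}

#' @rdname extract_occlusions
#' @param path File path for the records CSV.
#' @export
write_occlusion_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
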