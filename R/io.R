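# Plain-text persistence: traces and cohort manifests as CSV.

#' Write / read a trace as CSV
#'
#' Columns `time_s`, `fhr_bpm` and (when present) `fbp_mmhg`; missing
#' samples are empty cells. Trace metadata (sheep id, group,
#' first-occlusion start) travels in the cohort manifest, not the CSV.
#'
#' @param trace An `experiment_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = seq_along(trace$fhr) - 1L,
                   fhr_bpm = trace$fhr)
  if (!is.null(trace$fbp)) df$fbp_mmhg <- trace$fbp
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param first_occlusion_start,group,sheep_id Metadata to attach (usually
#'   taken from the cohort manifest).
#' @export
read_trace_csv <- function(path, first_occlusion_start = 0, group = NULL,
                           sheep_id = "sheep") {
  df <- utils::read.csv(path)
  stopifnot(all(diff(df$time_s) == 1))
  experiment_trace(df$fhr_bpm,
                   if ("fbp_mmhg" %in% names(df)) df$fbp_mmhg else NULL,
                   first_occlusion_start, group, sheep_id)
}

#' Cohort manifest
#'
#' One row per animal: `sheep_id`, `group`, `first_occlusion_start`.
#'
#' @param traces List of `experiment_trace`.
#' @export
cohort_manifest <- function(traces) {
  data.frame(
    sheep_id = vapply(traces, function(x) x$sheep_id, character(1)),
    group = vapply(traces, function(x) x$group$name, character(1)),
    first_occlusion_start = vapply(
      traces, function(x) x$first_occlusion_start, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname cohort_manifest
#' @param path File path for the manifest CSV.
#' @export
write_cohort_manifest <- function(traces, path) {
  utils::write.csv(cohort_manifest(traces), path, row.names = FALSE)
  invisible(path)
}
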