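# Time-offset augmentation, low-FBP duplication, normalisation and
# train/validation/test splitting.

#' Augmentation configuration
#'
#' @param offset_min,offset_max,offset_step Time offsets applied to each
#'   occlusion start, seconds: segments are re-sliced from 16 s before to
#'   16 s after the located start at 2 s intervals, giving 17 segments per
#'   occlusion.
#' @param dup_threshold Records labelled below this minimum FBP (mmHg) are
#'   duplicated in the training and validation sets.
#' @param dup_max Maximum number of duplication rounds (extra copies).
#' @param norm_sd Normalisation divisor, bpm: the overall SD of FHR across
#'   all segments of all animals (47.7 bpm for the experimental corpus).
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(offset_min = -16, offset_max = 16,
                                offset_step = 2, dup_threshold = 35,
                                dup_max = 5, norm_sd = 47.7) {
  cfg <- as.list(environment())
  stopifnot((cfg$offset_max - cfg$offset_min) / cfg$offset_step + 1 == 17,
            cfg$norm_sd > 0)
  class(cfg) <- "augmentation_config"
  cfg
}

#' Offsets implied by an augmentation configuration
#' @param cfg An `augmentation_config`.
#' @return Integer vector of offsets in seconds ({-16, -14, ..., 16}).
#' @export
augmentation_offsets <- function(cfg = augmentation_config()) {
  seq(cfg$offset_min, cfg$offset_max, by = cfg$offset_step)
}

#' Generate the 17 time-offset segments for one occlusion
#'
#' Each offset re-slices the trace at `start + offset` via
#' [slice_segment()]. Offsets that would run past a trace edge are clamped
#' to the valid range (the window shifts) so every occlusion contributes
#' exactly 17 segments.
#'
#' @param fhr 1 Hz FHR vector.
#' @param start Located occlusion start, seconds.
#' @param cfg An `augmentation_config`.
#' @param ecfg An `extraction_config`.
#' @return List with `offsets` (requested offsets, seconds) and `segments`
#'   (17 x 150 matrix; NA rows where a shifted segment was excluded for
#'   missing data).
#' @export
generate_offset_segments <- function(fhr, start,
                                     cfg = augmentation_config(),
                                     ecfg = extraction_config()) {
  offs <- augmentation_offsets(cfg)
  segs <- matrix(NA_real_, length(offs), ecfg$segment_length)
  max_start <- length(fhr) - ecfg$segment_length
  for (i in seq_along(offs)) {
    s <- min(max(start + offs[i], 0), max_start)
    sl <- slice_segment(fhr, s, ecfg)
    if (sl$status == "kept") segs[i, ] <- sl$segment
  }
  list(offsets = offs, segments = segs)
}

#' Normalise a segment
#'
#' Subtract the animal's baseline FHR and divide by the corpus-wide FHR
#' standard deviation, keeping deceleration and recovery gradients on a
#' common scale across animals.
#'
#' @param segment Numeric FHR values, bpm.
#' @param baseline Baseline FHR, bpm.
#' @param cfg An `augmentation_config` (supplies `norm_sd`).
#' @return Unitless values; invert with `x * norm_sd + baseline`.
#' @export
normalise_segment <- function(segment, baseline,
                              cfg = augmentation_config()) {
  stopifnot(is.finite(baseline))
  (segment - baseline) / cfg$norm_sd
}

#' Baseline FHR of one experiment trace
#'
#' Median FHR over all samples outside the occlusion windows. When no
#' non-occlusion sample exists the whole-trace median is used.
#'
#' @param fhr 1 Hz FHR vector.
#' @param occlusion_starts Occlusion start times, seconds.
#' @param occlusion_length Occlusion duration, seconds.
#' @return Baseline FHR, bpm.
#' @export
compute_sheep_baseline <- function(fhr, occlusion_starts,
                                   occlusion_length) {
  inside <- logical(length(fhr))
  for (s in occlusion_starts) {
    idx <- (s + 1):min(s + occlusion_length, length(fhr))
    inside[idx] <- TRUE
  }
  vals <- fhr[!inside]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) vals <- fhr[!is.na(fhr)]
  stats::median(vals)
}

#' Duplicate low-FBP records
#'
#' Records labelled below `dup_threshold` are over-sampled in whole rounds
#' (one extra copy of every below-threshold record per round), up to
#' `dup_max` rounds, stopping before any round that would leave more
#' records below the threshold than above it.
#'
#' @param entries Data.frame of dataset entries with a `label` column.
#' @param cfg An `augmentation_config`.
#' @return List `entries` (with duplicates appended) and `rounds` applied.
#' @export
duplicate_low_fbp <- function(entries, cfg = augmentation_config()) {
  below <- entries$label < cfg$dup_threshold
  b <- sum(below)
  a <- sum(!below)
  rounds <- 0L
  if (b > 0) {
    while (rounds < cfg$dup_max && b * (rounds + 2L) <= a) {
      rounds <- rounds + 1L
    }
  }
  if (rounds > 0) {
    dup <- entries[rep(which(below), rounds), , drop = FALSE]
    dup$is_duplicate <- TRUE
    entries <- rbind(entries, dup)
  }
  list(entries = entries, rounds = rounds)
}

#' Split configuration
#'
#' @param test_sheep_per_group Animals held out per group for the test set
#'   (optimisation mode); ignored when `test_sheep` names the held-out
#'   animal(s) directly (leave-one-out mode).
#' @param test_sheep Optional character vector of held-out animal ids.
#' @param bin_width Width of the minimum-FBP bins used to stratify the
#'   train/validation split, mmHg.
#' @param selection "random" (seeded) or "sequential" bin selection;
#'   leave-one-out evaluation uses "sequential".
#' @param seed Integer seed for random selection.
#' @return A `split_config` list. The train:validation ratio is fixed at
#'   5:1 (by occlusion, within each animal x FBP bin).
#' @export
split_config <- function(test_sheep_per_group = 2, test_sheep = NULL,
                         bin_width = 5, selection = c("random",
                                                      "sequential"),
                         seed = 1L) {
  selection <- match.arg(selection)
  structure(list(test_sheep_per_group = test_sheep_per_group,
                 test_sheep = test_sheep, bin_width = bin_width,
                 train_val_ratio = 5, selection = selection,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Build the augmented segment dataset from a cohort
#'
#' For every kept occlusion of every trace: slice the 17 time-offset
#' segments, normalise them against the animal's baseline FHR and attach
#' the single per-occlusion minimum-FBP label to all 17 offsets.
#'
#' @param traces List of `experiment_trace`.
#' @param ecfg An `extraction_config`.
#' @param acfg An `augmentation_config`.
#' @return A `segment_dataset`: list with `segments` (N x 150 matrix of
#'   normalised values), `meta` (data.frame: `sheep_id`, `group`,
#'   `occlusion_index`, `offset_s`, `label`, `is_duplicate`, `split`), and
#'   `records` (the per-occlusion record table across animals).
#' @export
build_segment_dataset <- function(traces, ecfg = extraction_config(),
                                  acfg = augmentation_config()) {
  seg_list <- list()
  meta_list <- list()
  rec_list <- list()
  for (trace in traces) {
    ex <- extract_occlusions(trace, ecfg)
    rec_list[[trace$sheep_id]] <- ex$records
    kept <- which(ex$records$status == "kept")
    if (!length(kept)) next
    baseline <- compute_sheep_baseline(
      trace$fhr, ex$records$start_time,
      trace$group$occlusion_length)
    for (i in kept) {
      off <- generate_offset_segments(trace$fhr,
                                      ex$records$start_time[i], acfg, ecfg)
      keep_rows <- !is.na(off$segments[, 1])
      segs <- normalise_segment(off$segments[keep_rows, , drop = FALSE],
                                baseline, acfg)
      key <- paste(trace$sheep_id, i, sep = ":")
      seg_list[[key]] <- segs
      meta_list[[key]] <- data.frame(
        sheep_id = trace$sheep_id,
        group = trace$group$name,
        occlusion_index = ex$records$occlusion_index[i],
        offset_s = off$offsets[keep_rows],
        label = ex$records$min_fbp[i],
        is_duplicate = FALSE,
        split = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(segments = do.call(rbind, seg_list),
                 meta = do.call(rbind, c(meta_list,
                                         make.row.names = FALSE)),
                 records = do.call(rbind, c(rec_list,
                                            make.row.names = FALSE))),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf(
    "<segment_dataset: %d segments, %d occlusions, %d animals>\n",
    nrow(x$segments),
    nrow(unique(x$meta[, c("sheep_id", "occlusion_index")])),
    length(unique(x$meta$sheep_id))))
  invisible(x)
}

# Occlusion-level train/val allocation within one (sheep x FBP bin) cell:
# 5:1 by occlusion, sequential = every 6th occlusion to validation.
allocate_bin <- function(occ_keys, selection, ratio = 5) {
  n <- length(occ_keys)
  if (selection == "sequential") {
    val <- occ_keys[seq_len(n) %% (ratio + 1) == 0]
  } else {
    n_val <- round(n / (ratio + 1))
    val <- if (n_val > 0) sample(occ_keys, n_val) else character(0)
  }
  val
}

#' Assign train/validation/test splits
#'
#' Test animals are held out whole (either `cfg$test_sheep`, or
#' `test_sheep_per_group` drawn at random per experimental group). The
#' remaining occlusions are binned by animal and by minimum-FBP bin and
#' allocated to training/validation at 5:1 within each bin, so both sets
#' see similar animals and label distributions. All 17 offsets of an
#' occlusion stay in one split. Low-FBP duplication is applied afterwards,
#' separately within the training and validation sets.
#'
#' @param dataset A `segment_dataset`.
#' @param cfg A `split_config`.
#' @param acfg An `augmentation_config` (duplication rule).
#' @param duplicate Apply low-FBP duplication to train/val (default TRUE).
#' @return The dataset with `meta$split` filled in (and duplicate rows
#'   appended), plus `dup_rounds` recording the rounds applied.
#' @export
make_splits <- function(dataset, cfg = split_config(),
                        acfg = augmentation_config(), duplicate = TRUE) {
  meta <- dataset$meta
  if (is.null(cfg$test_sheep)) {
    set.seed(cfg$seed)
    sheep_groups <- unique(meta[, c("sheep_id", "group")])
    test_sheep <- character(0)
    for (g in unique(sheep_groups$group)) {
      ids <- sheep_groups$sheep_id[sheep_groups$group == g]
      if (length(ids) < cfg$test_sheep_per_group) {
        stop("group ", g, " has fewer than ", cfg$test_sheep_per_group,
             " animals to draw a test set from")
      }
      test_sheep <- c(test_sheep, sample(ids, cfg$test_sheep_per_group))
    }
  } else {
    test_sheep <- cfg$test_sheep
    set.seed(cfg$seed)
  }

  meta$split <- ifelse(meta$sheep_id %in% test_sheep, "test",
                       NA_character_)
  occ_key <- paste(meta$sheep_id, meta$occlusion_index, sep = ":")
  non_test <- is.na(meta$split)
  occ <- unique(data.frame(key = occ_key[non_test],
                           sheep_id = meta$sheep_id[non_test],
                           label = meta$label[non_test],
                           stringsAsFactors = FALSE))
  occ <- occ[order(occ$key), ]
  occ$bin <- floor(occ$label / cfg$bin_width)
  val_keys <- character(0)
  for (cell in split(occ$key, list(occ$sheep_id, occ$bin), drop = TRUE)) {
    val_keys <- c(val_keys, allocate_bin(cell, cfg$selection,
                                         cfg$train_val_ratio))
  }
  meta$split[non_test] <- ifelse(occ_key[non_test] %in% val_keys,
                                 "val", "train")

  dataset$meta <- meta
  dataset$dup_rounds <- c(train = 0L, val = 0L)
  if (duplicate) {
    for (sp in c("train", "val")) {
      rows <- which(meta$split == sp)
      dup <- duplicate_low_fbp(meta[rows, , drop = FALSE], acfg)
      dataset$dup_rounds[[sp]] <- dup$rounds
      if (dup$rounds > 0) {
        extra <- dup$entries[-seq_along(rows), , drop = FALSE]
        extra_rows <- rep(rows[meta$label[rows] < acfg$dup_threshold],
                          dup$rounds)
        dataset$segments <- rbind(dataset$segments,
                                  dataset$segments[extra_rows, ,
                                                   drop = FALSE])
        dataset$meta <- rbind(dataset$meta, extra)
      }
    }
  }
  rownames(dataset$meta) <- NULL
  dataset$test_sheep <- test_sheep
  dataset
}
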