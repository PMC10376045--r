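test_that("17 offset segments per occlusion at 2 s intervals", {
  cfg <- augmentation_config()
  expect_equal(augmentation_offsets(cfg), seq(-16, 16, 2))

  fhr <- stats::rnorm(400, 140, 5) + 30 * sin(seq_len(400) / 20)
  off <- generate_offset_segments(fhr, 100)
  expect_equal(dim(off$segments), c(17, 150))
  # offset 0 equals the plain slice
  expect_equal(off$segments[9, ], slice_segment(fhr, 100)$segment)
  # offset -16 / +16 are shifted windows
  expect_equal(off$segments[1, ], fhr[(84 + 1):(84 + 150)])
  expect_equal(off$segments[17, ], fhr[(116 + 1):(116 + 150)])
})

test_that("offsets beyond the trace edge clamp instead of dropping", {
  fhr <- stats::rnorm(170, 140, 5)
  off <- generate_offset_segments(fhr, 10)   # -16 would start at -6
  expect_false(anyNA(off$segments))
  expect_equal(off$segments[1, ], fhr[1:150])   # clamped to start 0
})

test_that("dataset size is exactly 17 x kept occlusions before duplication", {
  ds <- small_dataset()
  n_kept <- sum(ds$records$status == "kept")
  expect_equal(nrow(ds$segments), 17 * n_kept)
  expect_equal(nrow(ds$meta), 17 * n_kept)
  # the single per-occlusion label is attached to all 17 offsets
  one <- ds$meta[ds$meta$sheep_id == ds$meta$sheep_id[1] &
                   ds$meta$occlusion_index == ds$meta$occlusion_index[1], ]
  expect_equal(nrow(one), 17)
  expect_equal(length(unique(one$label)), 1)
})

test_that("low-FBP duplication proceeds in whole rounds with the stop rule", {
  mk <- function(n_below, n_above) {
    data.frame(label = c(rep(20, n_below), rep(50, n_above)),
               is_duplicate = FALSE)
  }
  r1 <- duplicate_low_fbp(mk(10, 100))
  expect_equal(r1$rounds, 5)                      # 10 * 6 = 60 <= 100
  expect_equal(sum(r1$entries$label < 35), 60)

  r2 <- duplicate_low_fbp(mk(30, 40))             # one round would give 60 > 40
  expect_equal(r2$rounds, 0)
  expect_equal(nrow(r2$entries), 70)

  r3 <- duplicate_low_fbp(mk(0, 25))              # nothing below threshold
  expect_equal(r3$rounds, 0)
  expect_equal(nrow(r3$entries), 25)

  r4 <- duplicate_low_fbp(mk(20, 100))            # 20*(1+r) <= 100 -> r = 4
  expect_equal(r4$rounds, 4)
  expect_equal(sum(r4$entries$label < 35), 100)
})

test_that("normalisation subtracts baseline and divides by 47.7 bpm", {
  cfg <- augmentation_config()
  expect_equal(normalise_segment(rep(160, 150), 160), rep(0, 150))
  expect_equal(normalise_segment(112.3, 160), -1)
  seg <- stats::rnorm(150, 140, 20)
  norm <- normalise_segment(seg, 141.5)
  expect_equal(norm * cfg$norm_sd + 141.5, seg)    # invertible
})

test_that("sheep baseline is the median over non-occlusion samples", {
  fhr <- rep(160, 1000)
  expect_equal(compute_sheep_baseline(fhr, c(100, 400), 60), 160)
  fhr[c(101:160, 401:460)] <- 80                   # during occlusions
  expect_equal(compute_sheep_baseline(fhr, c(100, 400), 60), 160)
  # single occlusion ending at the trace end: pre-occlusion median
  fhr2 <- c(rep(150, 940), rep(80, 60))
  expect_equal(compute_sheep_baseline(fhr2, 940, 60), 150)
})

test_that("splits hold out whole animals and allocate 5:1 within bins", {
  ds <- small_dataset()
  sheep <- unique(ds$meta$sheep_id)
  split <- make_splits(ds, split_config(test_sheep = sheep[1],
                                        selection = "sequential"))
  m <- split$meta
  # test animal never appears in train or val
  expect_setequal(m$sheep_id[m$split == "test"], sheep[1])
  expect_false(sheep[1] %in% m$sheep_id[m$split %in% c("train", "val")])
  # all offsets and duplicates of an occlusion share one split
  key <- paste(m$sheep_id, m$occlusion_index)
  expect_true(all(tapply(m$split, key,
                         function(s) length(unique(s)) == 1)))
  # 5:1 ratio by occlusion within each (sheep x 5 mmHg bin), +/- 1
  non_test <- m[m$split != "test" & !m$is_duplicate, ]
  occ <- unique(data.frame(key = paste(non_test$sheep_id,
                                       non_test$occlusion_index),
                           sheep = non_test$sheep_id,
                           bin = floor(non_test$label / 5),
                           split = non_test$split))
  for (cell in split(occ, list(occ$sheep, occ$bin), drop = TRUE)) {
    n_val <- sum(cell$split == "val")
    expect_lte(abs(n_val - nrow(cell) / 6), 1)
  }
  # duplication balance: below never outnumbers above in train or in val
  for (sp in c("train", "val")) {
    lab <- m$label[m$split == sp]
    expect_lte(sum(lab < 35), sum(lab >= 35))
  }
})

test_that("random test-animal selection draws the required count per group", {
  groups <- sheep_group_table()
  groups$n_sheep <- rep(2L, 4)
  coh <- simulate_cohort(groups, sheep_sim_params(fhr_noise_sd = 1),
                         seed = 5)
  ds <- build_segment_dataset(coh)
  split <- make_splits(ds, split_config(test_sheep_per_group = 1,
                                        seed = 3), duplicate = FALSE)
  test_sheep <- unique(ds$meta$sheep_id[split$meta$split == "test"])
  expect_length(test_sheep, 4)     # one per group
  grp <- unique(ds$meta[, c("sheep_id", "group")])
  expect_setequal(grp$group[grp$sheep_id %in% test_sheep],
                  c("N1-5", "H1-5", "N1-2.5", "N2-5"))
  expect_error(make_splits(ds, split_config(test_sheep_per_group = 3)),
               "fewer than")
})
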