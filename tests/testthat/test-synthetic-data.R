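test_that("group table matches the four-group occlusion protocol", {
  tab <- sheep_group_table()
  expect_setequal(tab$name, c("N1-5", "H1-5", "N1-2.5", "N2-5"))
  g <- group_spec("N2-5")
  expect_equal(g$occlusion_length, 120)
  expect_equal(g$occlusion_spacing, 300)
  expect_equal(g$condition, "normoxic")
  expect_equal(group_spec("H1-5")$condition, "hypoxic")
  expect_true(all(tab$occlusion_length < tab$occlusion_spacing))
  expect_error(group_spec("N3-7"), "unknown")
})

test_that("simulated occlusions follow the group protocol spacing", {
  tr <- noiseless_trace("N2-5")
  starts <- locate_occlusion_starts(tr$first_occlusion_start, 300,
                                    length(tr$fhr))
  expect_equal(diff(starts), rep(300, length(starts) - 1))
  # every occlusion lasts 120 s: FHR is at its nadir just before the end
  # of the occlusion and recovering right after
  for (s in starts[1:3]) {
    expect_lt(tr$fhr[s + 119 + 1], tr$fhr[s + 140 + 1])
    expect_equal(tr$fhr[s + 60 + 1], tr$fhr[s + 119 + 1])  # still occluded
  }
})

test_that("same seed gives bit-identical traces; cohort is reproducible", {
  p <- sheep_sim_params(seed = 123)
  t1 <- simulate_sheep("N1-5", p)
  t2 <- simulate_sheep("N1-5", p)
  expect_identical(t1$fhr, t2$fhr)
  expect_identical(t1$fbp, t2$fbp)
  expect_identical(t1$truth_min_fbp, t2$truth_min_fbp)

  g <- sheep_group_table()[3, ]
  g$n_sheep <- 2L
  c1 <- simulate_cohort(g, seed = 9)
  c2 <- simulate_cohort(g, seed = 9)
  expect_identical(lapply(c1, `[[`, "fhr"), lapply(c2, `[[`, "fhr"))
  expect_length(c1, 2)
  expect_false(anyDuplicated(names(c1)) > 0)
})

test_that("experiment stops after two successive latent minima < 20 mmHg", {
  # fast hypotension: minima cross 20 mmHg well before the 4 h cap
  p <- sheep_sim_params(baseline_fbp = 55, hypotension_rate = 4,
                        fbp_jitter_sd = 0, fhr_noise_sd = 0,
                        gap_prob = 0, seed = 1)
  tr <- simulate_sheep("N1-5", p)
  m <- tr$truth_min_fbp
  K <- length(m)
  # by-hand application of the stop rule to the known latent sequence
  # 55 - 4k (clamped at 2): first pair below 20 at k = 9, 10
  expect_equal(m, pmin(pmax(55 - 4 * (0:10), 2), 55))
  expect_equal(K, 11)        # stops right after the k = 9, 10 pair < 20
  expect_equal(sum(m < 20), 2)
})

test_that("occlusion count never exceeds the 4 h protocol cap", {
  for (gname in c("N1-5", "N1-2.5")) {
    p <- sheep_sim_params(hypotension_rate = 0.05, seed = 3)
    tr <- simulate_sheep(gname, p)
    spacing <- tr$group$occlusion_spacing
    expect_lte(length(tr$truth_min_fbp), floor(4 * 3600 / spacing) + 1)
  }
})

test_that("deceleration nadir is positively coupled to the latent minimum FBP", {
  tr <- noiseless_trace("N1-5", seed = 21)
  starts <- locate_occlusion_starts(tr$first_occlusion_start, 300,
                                    length(tr$fhr))
  nadir <- vapply(starts,
                  function(s) min(tr$fhr[(s + 1):(s + 60)]), numeric(1))
  expect_gt(stats::cor(tr$truth_min_fbp, nadir), 0.9)
})

test_that("simulator rejects parameters that push FHR out of range", {
  expect_error(simulate_sheep("N1-5",
    sheep_sim_params(baseline_fhr = 100, coupling_depth = 3,
                     hypotension_rate = 2, seed = 1)), "below 30")
  expect_error(sheep_sim_params(baseline_fbp = 90), "baseline_fbp")
  expect_error(sheep_sim_params(coupling_depth = -1), "nonnegative")
})

test_that("post-occlusion overshoot appears only in N2-5 and H1-5", {
  for (gname in c("N1-5", "H1-5", "N2-5")) {
    p <- sheep_sim_params(fhr_noise_sd = 0, gap_prob = 0,
                          overshoot_gain = 20, seed = 4)
    tr <- simulate_sheep(gname, p)
    s <- tr$first_occlusion_start
    len <- tr$group$occlusion_length
    post <- tr$fhr[(s + len + 21):(s + len + 80)]
    if (gname == "N1-5") {
      expect_lte(max(post), p$baseline_fhr + 1e-9)
    } else {
      expect_gt(max(post), p$baseline_fhr + 5)
    }
  }
})

test_that("human trace: duration, determinism, severity coupling", {
  h <- simulate_human_trace(duration_s = 5400, severity = 0, seed = 2)
  expect_length(h$fhr, 5400)
  expect_false(h$outcome)
  h2 <- simulate_human_trace(duration_s = 5400, severity = 0, seed = 2)
  expect_identical(h$fhr, h2$fhr)

  sev <- simulate_human_trace(duration_s = 5400, severity = 1, seed = 2)
  expect_true(sev$outcome)
  expect_lt(mean(sev$truth_min_fbp), mean(h$truth_min_fbp))
  # deeper decelerations in the severe trace
  depth <- function(x) {
    bl <- stats::median(x$fhr, na.rm = TRUE)
    mean(vapply(x$decel_starts, function(s)
      bl - min(x$fhr[(s + 1):min(s + 90, length(x$fhr))], na.rm = TRUE),
      numeric(1)))
  }
  expect_gt(depth(sev), depth(h))
  # some onsets closer together than one segment length
  expect_true(any(diff(sort(sev$decel_starts)) < 150))
})

test_that("trace CSV round-trips including missing samples", {
  tr <- simulate_sheep("N1-5", sheep_sim_params(gap_prob = 0.01, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, tr$first_occlusion_start, tr$group,
                         tr$sheep_id)
  expect_equal(back$fhr, tr$fhr)
  expect_equal(back$fbp, tr$fbp)

  man <- cohort_manifest(list(tr))
  expect_equal(man$group, "N1-5")
  expect_equal(man$first_occlusion_start, tr$first_occlusion_start)
})
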