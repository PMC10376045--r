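test_that("deceleration detector finds known onsets and nothing on flat traces", {
  cfg <- human_config()
  flat <- rep(140, 3000) + stats::rnorm(3000, 0, 1)
  expect_equal(nrow(detect_decelerations(flat, cfg = cfg)), 0)

  # single synthetic deceleration: 40 bpm deep, 60 s, onset at 1000 s
  h <- simulate_human_trace(duration_s = 3000, severity = 0,
                            fhr_noise_sd = 1, gap_prob = 0, seed = 5,
                            mean_gap_s = 1e9)   # suppress random onsets
  fhr <- h$fhr
  s0 <- 1000
  depth <- 40
  for (dt in 0:74) {
    v <- if (dt < 15) 140 - depth * dt / 15
         else if (dt < 60) 140 - depth
         else 140 - depth + depth * (dt - 60 + 1) / 15
    fhr[s0 + dt + 1] <- v
  }
  dec <- detect_decelerations(fhr, cfg = cfg)
  expect_equal(nrow(dec), 1)
  expect_lte(abs(dec$start[1] - s0), 10)

  # generator ground truth with well-separated contractions (overlapping
  # decelerations merge into single runs, where onset matching is
  # ill-posed): one detection per true onset, each within 10 s
  h2 <- simulate_human_trace(duration_s = 2000, severity = 0.3,
                             fhr_noise_sd = 1, gap_prob = 0,
                             mean_gap_s = 300, seed = 39)
  dec2 <- detect_decelerations(h2$fhr, cfg = cfg)
  expect_equal(nrow(dec2), length(h2$decel_starts))
  expect_true(all(abs(dec2$start - h2$decel_starts) <= 10))
})

test_that("human baseline: 15-min-window median robust to decelerations", {
  cfg <- human_config()
  expect_equal(compute_human_baseline(rep(140, 3000), 1500, cfg), 140)
  # a 60 s dip inside the window barely moves the median
  fhr <- rep(140, 3000)
  fhr[1401:1460] <- 100
  expect_equal(compute_human_baseline(fhr, 1500, cfg), 140)
  # window clipped near the trace start is still defined
  expect_equal(compute_human_baseline(rep(140, 3000), 100, cfg), 140)
  expect_error(compute_human_baseline(rep(NA_real_, 3000), 1500, cfg),
               "fully missing")
})

test_that("human prediction pipeline attaches covariates and skips bad segments", {
  model <- sheep_trained_model()
  cfg <- human_config()

  # flat trace: no decelerations, empty result
  flat <- list(fhr = rep(140, 3000) + stats::rnorm(3000, 0, 1),
               trace_id = "flat")
  expect_equal(nrow(predict_human(flat, model, cfg)), 0)

  h <- simulate_human_trace(duration_s = 5400, severity = 0.4,
                            gap_prob = 0.002, seed = 8, trace_id = "ctg-8")
  preds <- predict_human(h, model, cfg)
  expect_gt(nrow(preds), 0)
  expect_true(all(preds$predicted_min_fbp >= 0))
  expect_true(all(diff(preds$start_time) > 0))
  expect_true(!is.unsorted(preds$n_prior_decels, strictly = TRUE))
  expect_equal(preds$time_to_end, 5400 - preds$start_time)
})

test_that("severe synthetic cohort gets lower predictions than non-severe", {
  model <- sheep_trained_model()
  cfg <- human_config()
  pred_means <- function(severity, seeds) {
    unlist(lapply(seeds, function(s) {
      h <- simulate_human_trace(severity = severity, seed = s,
                                trace_id = paste0("ctg-", s))
      predict_human(h, model, cfg)$predicted_min_fbp
    }))
  }
  lo <- pred_means(0, 1:4)
  hi <- pred_means(1, 1:4)
  expect_gt(mean(lo), mean(hi))
  cmpr <- compare_groups(lo, hi)
  expect_lt(cmpr$mean_difference, 0)
})

test_that("group comparison statistics match reference implementations", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$mean_difference, 0)
  set.seed(15)
  a <- stats::rnorm(80, 40, 5)
  b <- a - 0.5
  cmpr <- compare_groups(a, b)
  expect_equal(cmpr$mean_difference, -0.5)
  expect_equal(unname(cmpr$quartile_differences), rep(-0.5, 3))

  # Welch t statistic by hand
  x <- stats::rnorm(60, 40, 6)
  y <- stats::rnorm(50, 37, 4)
  cm <- compare_groups(x, y)
  tstat <- (mean(y) - mean(x)) /
    sqrt(stats::var(y) / length(y) + stats::var(x) / length(x))
  df <- (stats::var(y) / 50 + stats::var(x) / 60)^2 /
    ((stats::var(y) / 50)^2 / 49 + (stats::var(x) / 60)^2 / 59)
  p_hand <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(cm$t_test_p, p_hand, tolerance = 1e-9)
  expect_true(cm$mann_whitney_p > 0 && cm$mann_whitney_p < 1)

  # degenerate constant samples are flagged
  dg <- compare_groups(rep(4, 5), rep(4, 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t_test_p))

  # null calibration: same distribution, p rarely tiny
  set.seed(16)
  ps <- replicate(20, {
    compare_groups(stats::rnorm(100, 40, 5),
                   stats::rnorm(100, 40, 5))$t_test_p
  })
  expect_gt(mean(ps > 0.01), 0.8)
})

test_that("trend summaries bin predictions against covariates", {
  # constant predictions: flat trend
  preds <- data.frame(predicted_min_fbp = rep(40, 60),
                      n_prior_decels = rep(0:19, 3),
                      time_to_end = seq(5400, 60, length.out = 60))
  tr <- trend_summary(preds, "n_prior_decels", bins = 5)
  expect_true(all(tr$mean_prediction == 40))

  # predictions linear in the covariate: binned means linear
  preds$predicted_min_fbp <- 50 - 0.5 * preds$n_prior_decels
  tr2 <- trend_summary(preds, "n_prior_decels", bins = 4)
  expect_equal(tr2$mean_prediction,
               50 - 0.5 * as.numeric(
                 tapply(preds$n_prior_decels,
                        cut(preds$n_prior_decels,
                            seq(0, 19, length.out = 5),
                            include.lowest = TRUE), mean)))
  expect_lt(tr2$mean_prediction[nrow(tr2)], tr2$mean_prediction[1])
})
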