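# Shared fixtures. Heavier objects (small trained models, cohorts) are
# built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# brute-force percentile: linear interpolation between order statistics,
# written out by hand (independent of stats::quantile)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# noiseless single-sheep trace
noiseless_trace <- function(group = "N1-5", seed = 7, ...) {
  p <- sheep_sim_params(fhr_noise_sd = 0, gap_prob = 0, fbp_noise_sd = 0,
                        seed = seed, ...)
  simulate_sheep(group, p)
}

# two-animal mildly noisy dataset for pipeline tests
small_dataset <- function() {
  fixture("small_dataset", function() {
    t1 <- simulate_sheep("N1-5",
                         sheep_sim_params(fhr_noise_sd = 1,
                                          gap_prob = 0.002, seed = 5),
                         sheep_id = "N1-5-01")
    t2 <- simulate_sheep("N1-2.5",
                         sheep_sim_params(fhr_noise_sd = 1,
                                          gap_prob = 0.002,
                                          baseline_fbp = 50,
                                          hypotension_rate = 0.6,
                                          seed = 6),
                         sheep_id = "N1-2.5-01")
    build_segment_dataset(list(t1, t2))
  })
}

# reduced architecture + training settings used throughout the tests:
# small problem sizes keep the suite quick while exercising the full
# conv/pool/batch-norm/dense stack
test_model_config <- function() {
  model_config(conv_blocks = list(c(8, 5, 2), c(16, 5, 2)),
               dense_sizes = 32)
}

test_train_config <- function(...) {
  args <- list(learning_rate = 3e-3, patience = 30, batch_size = 128,
               max_epochs = 120, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

# one model trained on a small full cohort (no test sheep): reused by the
# human-application tests
sheep_trained_model <- function() {
  fixture("sheep_trained_model", function() {
    groups <- sheep_group_table()
    groups$n_sheep <- c(2L, 1L, 2L, 1L)
    coh <- simulate_cohort(groups,
                           sheep_sim_params(coupling_depth = 1.5,
                                            fhr_noise_sd = 1,
                                            gap_prob = 0.002,
                                            fbp_noise_sd = 0.5),
                           seed = 77)
    ds <- build_segment_dataset(coh)
    ds <- make_splits(ds, split_config(test_sheep = character(0),
                                       selection = "sequential",
                                       seed = 11))
    train_on_dataset(ds, test_model_config(),
                     test_train_config(max_epochs = 80))
  })
}
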