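test_that("model shape contract: scalar nonnegative output per segment", {
  cfg <- test_model_config()
  m <- build_model(cfg, seed = 1)
  set.seed(2)
  X <- matrix(stats::rnorm(5 * 150), 5)
  p <- predict_min_fbp(m, X)
  expect_length(p, 5)
  expect_true(all(p >= 0))
  expect_error(predict_min_fbp(m, matrix(0, 2, 100)), "expects")
  # batch order preserved
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict_min_fbp(m, X[perm, ]), p[perm])
})

test_that("a zero-weight model predicts the 40 mmHg output bias everywhere", {
  cfg <- test_model_config()
  m <- build_model(cfg, seed = 1)
  zero <- utils::relist(unlist(m$params) * 0, m$params)
  for (i in seq_along(zero$conv)) {
    zero$conv[[i]]$gamma <- rep(1, length(zero$conv[[i]]$gamma))
  }
  zero$dense[[length(zero$dense)]]$b <- 40
  m$params <- zero
  set.seed(3)
  expect_equal(predict_min_fbp(m, matrix(stats::rnorm(3 * 150), 3)),
               rep(40, 3))
})

test_that("fresh models start predicting near the 40 mmHg bias", {
  m <- build_model(test_model_config(), seed = 5)
  set.seed(4)
  p <- predict_min_fbp(m, matrix(stats::rnorm(20 * 150, 0, 0.5), 20))
  expect_true(all(abs(p - 40) < 15))
})

test_that("MAPE agrees with the by-hand formula", {
  expect_equal(mape_loss(c(45, 45), c(40, 50)), 11.25)
  expect_equal(mape_loss(80, 40), 100)
  expect_equal(mape_loss(c(40, 50), c(40, 50)), 0)
  # brute-force oracle on random vectors
  set.seed(6)
  for (i in 1:20) {
    y <- stats::runif(50, 10, 80)
    p <- y + stats::rnorm(50, 0, 5)
    brute <- sum(vapply(seq_along(y),
                        function(j) 100 * abs(p[j] - y[j]) / y[j],
                        numeric(1))) / 50
    expect_equal(mape_loss(p, y), brute, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences through every layer", {
  cfg <- model_config(conv_blocks = list(c(2, 3, 2), c(3, 3, 2)),
                      dense_sizes = 4, input_len = 16,
                      output_bias_init = 5)
  m <- build_model(cfg, seed = 2)
  set.seed(9)
  # jitter every parameter off zero: freshly initialised biases put dead
  # samples exactly on the ReLU corner, where one-sided finite differences
  # disagree with the (valid) zero subgradient
  m$params <- utils::relist(
    unlist(m$params) + stats::rnorm(length(unlist(m$params)), 0, 0.05),
    m$params)
  X <- matrix(stats::rnorm(6 * 16), 6)
  y <- stats::runif(6, 30, 50)
  lg <- decelfbp:::.cpp_loss_grad(m$params, m$buffers, X, y, unclass(cfg))
  g_analytic <- unlist(lg$grads)
  par_vec <- unlist(m$params)
  eps <- 1e-6
  g_num <- vapply(seq_along(par_vec), function(i) {
    vp <- par_vec; vp[i] <- vp[i] + eps
    vm <- par_vec; vm[i] <- vm[i] - eps
    lp <- decelfbp:::.cpp_loss_grad(utils::relist(vp, m$params),
                                    m$buffers, X, y, unclass(cfg))$loss
    lm <- decelfbp:::.cpp_loss_grad(utils::relist(vm, m$params),
                                    m$buffers, X, y, unclass(cfg))$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g_analytic - g_num)), 1e-5)
})

test_that("the trainer can overfit a tiny noiseless set (capacity check)", {
  # 20 segments with a monotone segment -> label mapping
  set.seed(10)
  depth <- seq(0.2, 1.6, length.out = 20)
  X <- t(vapply(depth, function(d) {
    s <- rep(0, 150); s[20:80] <- -d; s
  }, numeric(150)))
  y <- 60 - 25 * depth
  m <- build_model(model_config(conv_blocks = list(c(4, 5, 2)),
                                dense_sizes = 8), seed = 3)
  tcfg <- train_config(learning_rate = 5e-3, patience = 100,
                       batch_size = 20, max_epochs = 400, seed = 3)
  fit <- train_model(m, X, y, X, y, tcfg)
  expect_lt(mape_loss(predict_min_fbp(fit, X), y), 5)
  # consistency with recorded history: restored weights reproduce the
  # best validation MAPE (train == val here)
  expect_equal(mape_loss(predict_min_fbp(fit, X), y),
               fit$history$best_val_mape, tolerance = 1e-8)
})

test_that("early stopping halts after the patience window", {
  set.seed(11)
  X <- matrix(stats::rnorm(30 * 150, 0, 0.1), 30)
  y <- rep(40, 30)
  m <- build_model(model_config(conv_blocks = list(c(2, 5, 4)),
                                dense_sizes = 4), seed = 4)
  # a dead ReLU output (negative bias) predicts exactly 0 and passes no
  # gradient, so the validation MAPE is frozen at 100% and the halt must
  # come exactly `patience` epochs after the first (best) epoch
  m$params$dense[[length(m$params$dense)]]$b <- -5
  tcfg <- train_config(learning_rate = 1e-3, patience = 10,
                       batch_size = 30, max_epochs = 500, seed = 4)
  fit <- train_model(m, X, y, X, y, tcfg)
  h <- fit$history
  expect_equal(h$halted_epoch, h$best_epoch + 10)
  expect_equal(h$best_val_mape, 100)
  expect_equal(min(h$val_mape), 100)
})

test_that("training is deterministic given the seed", {
  ds <- small_dataset()
  sheep <- unique(ds$meta$sheep_id)
  sp <- make_splits(ds, split_config(test_sheep = sheep[2],
                                     selection = "sequential"))
  tcfg <- test_train_config(max_epochs = 5, patience = 5)
  f1 <- train_on_dataset(sp, test_model_config(), tcfg)
  f2 <- train_on_dataset(sp, test_model_config(), tcfg)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$history$val_mape, f2$history$val_mape)
})
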