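# CNN regressor: configuration, initialisation, training with early
# stopping, prediction. The numerics live in src/cnn.cpp; all randomness
# (weight init, batch shuffling) goes through R's RNG so a seed fully
# determines training.

#' CNN architecture configuration
#'
#' Each convolutional block is convolution -> max-pool -> batch-norm (with
#' ReLU after the batch-norm); the flattened features feed dense ReLU
#' layers and a single ReLU output unit whose bias starts at
#' `output_bias_init` so that initial predictions sit near the mean
#' minimum FBP.
#'
#' @param conv_blocks List of `c(n_filters, kernel_size, pool_size)`.
#' @param dense_sizes Hidden dense-layer sizes (the 1-unit output layer is
#'   appended automatically).
#' @param input_len Segment length in samples.
#' @param output_bias_init Initial output bias, on the mmHg scale.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_blocks = list(c(16, 5, 2), c(32, 5, 2),
                                            c(64, 5, 2)),
                         dense_sizes = 64, input_len = 150,
                         output_bias_init = 40) {
  stopifnot(length(conv_blocks) >= 1)
  cfg <- list(
    n_filters = vapply(conv_blocks, `[`, numeric(1), 1),
    kernel_size = vapply(conv_blocks, `[`, numeric(1), 2),
    pool_size = vapply(conv_blocks, `[`, numeric(1), 3),
    dense_sizes = as.integer(dense_sizes),
    input_len = as.integer(input_len),
    output_bias_init = output_bias_init
  )
  # check the feature map survives every block
  len <- cfg$input_len
  for (i in seq_along(cfg$n_filters)) {
    len <- floor((len - cfg$kernel_size[i] + 1) / cfg$pool_size[i])
    if (len < 1) stop("conv block ", i, " reduces the feature map to ",
                      "nothing; shrink kernels/pools")
  }
  cfg$flat_len <- len
  class(cfg) <- "model_config"
  cfg
}

#' Training configuration
#'
#' @param learning_rate ADAM learning rate.
#' @param loss Loss function; only "mape" (mean absolute percentage error)
#'   is provided, chosen so errors on the lowest blood pressures carry the
#'   largest penalty.
#' @param patience Early-stopping patience: training halts when validation
#'   MAPE has not improved for this many epochs.
#' @param batch_size Mini-batch size.
#' @param max_epochs Hard cap on training epochs.
#' @param eval_interval Validation evaluation interval, epochs.
#' @param bn_momentum Batch-norm running-statistics momentum.
#' @param seed Integer seed (weight init + batch shuffling).
#' @return A `train_config` list (optimiser is always ADAM).
#' @export
train_config <- function(learning_rate = 1e-4, loss = "mape",
                         patience = 50, batch_size = 64,
                         max_epochs = 2000, eval_interval = 1,
                         bn_momentum = 0.9, seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1, loss == "mape")
  structure(list(optimiser = "adam", learning_rate = learning_rate,
                 loss = loss, patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 eval_interval = as.integer(eval_interval),
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_config")
}

# He (fan-in) initialised parameter set; zero ADAM state of the same shape.
init_params <- function(cfg, zero = FALSE, bias_init = 0) {
  draw <- function(nr, nc, fan_in) {
    if (zero) matrix(0, nr, nc)
    else matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  conv <- list()
  c_in <- 1L
  for (i in seq_along(cfg$n_filters)) {
    K <- cfg$kernel_size[i]
    F_ <- cfg$n_filters[i]
    conv[[i]] <- list(W = draw(K * c_in, F_, K * c_in),
                      b = numeric(F_),
                      gamma = if (zero) numeric(F_) else rep(1, F_),
                      beta = numeric(F_))
    c_in <- F_
  }
  sizes <- c(cfg$flat_len * c_in, cfg$dense_sizes, 1L)
  dense <- list()
  for (j in seq_len(length(sizes) - 1)) {
    dense[[j]] <- list(W = draw(sizes[j], sizes[j + 1], sizes[j]),
                       b = numeric(sizes[j + 1]))
  }
  if (!zero) dense[[length(dense)]]$b <- bias_init
  list(conv = conv, dense = dense)
}

#' Build an untrained CNN
#'
#' @param cfg A `model_config`.
#' @param seed Integer seed for the weight initialisation.
#' @return An `fbp_model`: configuration, parameters (He-initialised, output
#'   bias at `output_bias_init`), batch-norm running statistics, and an
#'   empty training history.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  params <- init_params(cfg, bias_init = cfg$output_bias_init)
  nb <- length(cfg$n_filters)
  buffers <- list(
    running_mean = lapply(seq_len(nb),
                          function(i) numeric(cfg$n_filters[i])),
    running_var = lapply(seq_len(nb),
                         function(i) rep(1, cfg$n_filters[i]))
  )
  structure(list(cfg = cfg, params = params, buffers = buffers,
                 history = NULL, seed = as.integer(seed)),
            class = "fbp_model")
}

#' @export
print.fbp_model <- function(x, ...) {
  blocks <- paste(sprintf("conv%g(k%g,p%g)", x$cfg$n_filters,
                          x$cfg$kernel_size, x$cfg$pool_size),
                  collapse = " -> ")
  cat("<fbp_model: ", blocks, " -> dense(",
      paste(x$cfg$dense_sizes, collapse = ","), ") -> 1",
      if (!is.null(x$history)) sprintf(" | best val MAPE %.2f%% @ epoch %d",
                                       x$history$best_val_mape,
                                       x$history$best_epoch),
      ">\n", sep = "")
  invisible(x)
}

#' Mean absolute percentage error
#'
#' `mean(100 * |pred - label| / label)`, the training loss. Labels are
#' guarded away from zero (discard rules guarantee labels of at least
#' 10 mmHg in practice).
#'
#' @param predictions,labels Numeric vectors, mmHg.
#' @return MAPE in percent.
#' @export
mape_loss <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), length(labels) > 0)
  mean(100 * abs(predictions - labels) / pmax(abs(labels), 1e-6))
}

#' Predict minimum FBP for normalised segments
#'
#' @param model A (trained) `fbp_model`.
#' @param segments Matrix of normalised 150-sample segments (rows), or one
#'   segment as a vector. Must be normalised exactly as in training.
#' @return Nonnegative predictions, mmHg, in batch order.
#' @export
predict_min_fbp <- function(model, segments) {
  if (is.vector(segments)) segments <- matrix(segments, 1)
  if (ncol(segments) != model$cfg$input_len) {
    stop("segments have ", ncol(segments), " samples; model expects ",
         model$cfg$input_len)
  }
  as.numeric(.cpp_predict(model$params, model$buffers, segments,
                          unclass(model$cfg)))
}

#' Train the CNN with ADAM, MAPE loss and early stopping
#'
#' Gradient training on mini-batches; validation MAPE is evaluated every
#' `eval_interval` epochs, the parameters at the validation minimum are
#' kept, and training halts once validation MAPE has not improved for
#' `patience` epochs (or at `max_epochs`). The returned model carries the
#' restored best parameters and a `training_history`.
#'
#' @param model An `fbp_model` from [build_model()].
#' @param train_x,train_y Training segments (matrix) and labels (mmHg).
#' @param val_x,val_y Validation segments and labels.
#' @param cfg A `train_config`.
#' @param verbose Print progress every 25 epochs.
#' @return The trained `fbp_model` (history in `$history`).
#' @export
train_model <- function(model, train_x, train_y, val_x, val_y,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(nrow(train_x) == length(train_y), length(train_y) > 0,
            nrow(val_x) == length(val_y), length(val_y) > 0)
  set.seed(cfg$seed)
  params <- model$params
  buffers <- model$buffers
  adam_m <- init_params(model$cfg, zero = TRUE)
  adam_v <- init_params(model$cfg, zero = TRUE)
  step <- 0L

  best <- list(val = Inf, epoch = 0L, params = params, buffers = buffers)
  hist_epoch <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_y))
    st <- .cpp_train_epoch(params, adam_m, adam_v, step, buffers,
                           train_x, train_y, ord, unclass(model$cfg),
                           cfg$learning_rate, cfg$batch_size,
                           cfg$bn_momentum)
    params <- st$params
    adam_m <- st$adam_m
    adam_v <- st$adam_v
    buffers <- st$buffers
    step <- st$step
    if (!is.finite(st$train_loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }

    if (epoch %% cfg$eval_interval == 0) {
      val_pred <- .cpp_predict(params, buffers, val_x,
                               unclass(model$cfg))
      val_mape <- mape_loss(as.numeric(val_pred), val_y)
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, st$train_loss)
      hist_val <- c(hist_val, val_mape)
      if (val_mape < best$val) {
        best <- list(val = val_mape, epoch = epoch, params = params,
                     buffers = buffers)
      }
      if (verbose && epoch %% 25 == 0) {
        message(sprintf("epoch %4d  train %6.2f%%  val %6.2f%%  best %6.2f%%",
                        epoch, st$train_loss, val_mape, best$val))
      }
      if (epoch - best$epoch >= cfg$patience * cfg$eval_interval) break
    }
  }

  model$params <- best$params
  model$buffers <- best$buffers
  model$history <- structure(
    list(epoch = hist_epoch, train_mape = hist_train,
         val_mape = hist_val, best_epoch = best$epoch,
         best_val_mape = best$val, halted_epoch = epoch),
    class = "training_history")
  model
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf(
    "<training_history: %d epochs, best val MAPE %.2f%% @ epoch %d>\n",
    x$halted_epoch, x$best_val_mape, x$best_epoch))
  invisible(x)
}

#' Train on a split segment dataset
#'
#' Convenience wrapper: pulls the train/val entries out of a split
#' `segment_dataset` and calls [train_model()].
#'
#' @param dataset A `segment_dataset` after [make_splits()].
#' @param mcfg A `model_config`.
#' @param tcfg A `train_config`.
#' @param verbose Passed through.
#' @return A trained `fbp_model`.
#' @export
train_on_dataset <- function(dataset, mcfg = model_config(),
                             tcfg = train_config(), verbose = FALSE) {
  tr <- dataset$meta$split == "train"
  va <- dataset$meta$split == "val"
  if (!any(va)) stop("dataset has no validation entries")
  model <- build_model(mcfg, seed = tcfg$seed)
  train_model(model,
              dataset$segments[tr, , drop = FALSE],
              dataset$meta$label[tr],
              dataset$segments[va, , drop = FALSE],
              dataset$meta$label[va],
              tcfg, verbose)
}
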