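#' Estimator configuration
#'
#' Describes one of the two architectures. The full-size defaults follow the
#' reference design: 4 hidden layers of 256 units (dense for the feedforward
#' network, LSTM cells for the recurrent one) with a dropout layer between
#' each, `tanh` hidden activations, a `sigmoid` output layer of 101 units,
#' MSE loss and the Adam optimizer. Dropout rate, learning rate, batch size,
#' epoch budget and early-stopping patience are not architecture-defining
#' and are exposed as knobs with the defaults below.
#'
#' @param architecture `"fnn"` or `"lstm"`.
#' @param hidden_layers Number of hidden layers (>= 1, default 4).
#' @param hidden_units Units per hidden layer (default 256).
#' @param dropout_rate Dropout probability in `[0, 1)` (default 0.2).
#' @param hidden_activation,output_activation Activation names; only
#'   `"tanh"` / `"sigmoid"` are supported.
#' @param optimizer Only `"adam"` is supported.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 300).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 25); 0 disables early stopping.
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout; training is bit-reproducible given the seed.
#' @param lstm_head How the LSTM output sequence feeds the sigmoid readout:
#'   `"sequence"` (default) applies one shared dense unit to every phase
#'   step's hidden state, producing the 101 outputs step by step;
#'   `"final"` feeds only the last step's hidden state into a dense layer of
#'   all 101 outputs. The sequence head avoids squeezing the whole stride
#'   through the final state and trains markedly better; see the methods
#'   vignette. Ignored for the feedforward network.
#' @return Object of class `model_config`.
#' @export
model_config <- function(architecture = c("fnn", "lstm"),
                         hidden_layers = 4, hidden_units = 256,
                         dropout_rate = 0.2,
                         hidden_activation = "tanh",
                         output_activation = "sigmoid",
                         optimizer = "adam",
                         learning_rate = 1e-3, batch_size = 32,
                         max_epochs = 300, early_stop_patience = 25,
                         seed = 1, lstm_head = c("sequence", "final")) {
  lstm_head <- match.arg(lstm_head)
  architecture <- match.arg(architecture)
  if (hidden_layers < 1) stop("model_config: hidden_layers must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("model_config: dropout_rate must be in [0, 1)")
  if (hidden_activation != "tanh") stop("model_config: only 'tanh' hidden activation is supported")
  if (output_activation != "sigmoid") stop("model_config: only 'sigmoid' output activation is supported")
  if (optimizer != "adam") stop("model_config: only the 'adam' optimizer is supported")
  structure(list(architecture = architecture,
                 hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 lstm_head = lstm_head),
            class = "model_config")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Build an untrained estimator
#'
#' Initializes the weights for the configured architecture. The feedforward
#' network consumes the flattened 101 x 24 feature block (2424 inputs); the
#' LSTM consumes the 101-step sequence of 24-channel vectors and collapses it
#' at the final step (its last hidden state feeds the dense sigmoid readout
#' of 101 units). Weights are Glorot-uniform; LSTM forget-gate biases start
#' at 1.
#'
#' @param config A [model_config()].
#' @param input_shape `c(n_phase_points, n_channels)`, default `c(101, 24)`.
#' @param n_outputs Output length (default 101).
#' @return Object of class `gaitemg_estimator` (untrained).
#' @export
build_estimator <- function(config, input_shape = c(101, 24), n_outputs = 101) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture == "lstm" && config$lstm_head == "sequence" &&
      input_shape[1] != n_outputs) {
    stop("build_estimator: the sequence readout emits one value per phase step; ",
         "input_shape[1] must equal n_outputs")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  H <- config$hidden_units
  L <- config$hidden_layers
  weights <- if (config$architecture == "fnn") {
    d <- prod(input_shape)
    dims <- c(d, rep(H, L), n_outputs)
    list(W = lapply(seq_len(L + 1), function(l) glorot(dims[l], dims[l + 1])),
         b = lapply(seq_len(L + 1), function(l) matrix(0, 1, dims[l + 1])))
  } else {
    C <- input_shape[2]
    ins <- c(C, rep(H, L - 1))
    b0 <- matrix(0, 1, 4 * H)
    b0[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
    seq_head <- config$lstm_head == "sequence"
    list(Wx = lapply(ins, function(ci) glorot(ci, 4 * H)),
         Wh = lapply(seq_len(L), function(l) glorot(H, 4 * H)),
         b = lapply(seq_len(L), function(l) b0),
         Wd = if (seq_head) glorot(H, 1) else glorot(H, n_outputs),
         bd = if (seq_head) matrix(0, 1, 1) else matrix(0, 1, n_outputs))
  }
  structure(list(config = config, input_shape = input_shape,
                 n_outputs = n_outputs, weights = weights,
                 trained = FALSE, muscle = NULL, history = NULL),
            class = "gaitemg_estimator")
}

#' Number of trainable parameters
#'
#' @param estimator A `gaitemg_estimator`.
#' @return Integer parameter count over all weight matrices and biases.
#' @export
count_parameters <- function(estimator) {
  sum(vapply(unlist(estimator$weights, recursive = FALSE), length, integer(1)))
}

#' Train an estimator on feature/target matrices
#'
#' Minimizes MSE with Adam on the training set, monitoring the validation
#' loss each epoch; training stops after `early_stop_patience` epochs without
#' improvement and the best-validation weights are kept. Aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param estimator An untrained (or previously trained) `gaitemg_estimator`.
#' @param train,validation Matrix bundles from [samples_to_matrices()].
#' @param muscle Muscle name recorded on the fitted model.
#' @return The estimator with fitted weights and a `history` data frame of
#'   per-epoch train/validation loss.
#' @export
fit_estimator <- function(estimator, train, validation, muscle = NULL) {
  stopifnot(inherits(estimator, "gaitemg_estimator"))
  cfg <- estimator$config
  w <- estimator$weights
  fit <- if (cfg$architecture == "fnn") {
    cpp_fnn_train(train$X, train$Y, validation$X, validation$Y,
                  w$W, w$b, cfg$dropout_rate, cfg$learning_rate,
                  cfg$batch_size, cfg$max_epochs, cfg$early_stop_patience,
                  cfg$seed)
  } else {
    cpp_lstm_train(seq_cube(train$A), train$Y, seq_cube(validation$A), validation$Y,
                   w$Wx, w$Wh, w$b, w$Wd, w$bd,
                   cfg$dropout_rate, cfg$learning_rate,
                   cfg$batch_size, cfg$max_epochs, cfg$early_stop_patience,
                   cfg$seed, cfg$lstm_head == "sequence")
  }
  estimator$weights <- if (cfg$architecture == "fnn") {
    list(W = fit$W, b = fit$b)
  } else {
    list(Wx = fit$Wx, Wh = fit$Wh, b = fit$b, Wd = fit$Wd, bd = fit$bd)
  }
  estimator$trained <- TRUE
  estimator$muscle <- muscle
  estimator$history <- data.frame(epoch = seq_along(fit$train_loss),
                                  train_loss = fit$train_loss,
                                  val_loss = fit$val_loss)
  estimator$best_epoch <- fit$best_epoch
  estimator
}

#' Train an estimator for one muscle from a dataset split
#'
#' @param estimator A `gaitemg_estimator`.
#' @param split A [split_dataset()] result with non-empty train and
#'   validation groups.
#' @param muscle Muscle whose normalized envelope is the target.
#' @return Trained estimator; see [fit_estimator()].
#' @export
train_estimator <- function(estimator, split, muscle) {
  if (!length(split$train) || !length(split$validation)) {
    stop("train_estimator: split must have non-empty train and validation groups")
  }
  if (!muscle %in% names(split$train[[1]]$targets)) {
    stop("train_estimator: no target envelope for muscle '", muscle, "'")
  }
  fit_estimator(estimator,
                samples_to_matrices(split$train, muscle),
                samples_to_matrices(split$validation, muscle),
                muscle = muscle)
}

# R array (n x C x T) -> arma cube with slices = phase steps
seq_cube <- function(A) {
  stopifnot(length(dim(A)) == 3L)
  A
}

#' Predict normalized envelopes
#'
#' @param object A trained `gaitemg_estimator`.
#' @param newdata A matrix bundle from [samples_to_matrices()], a list of
#'   `gait_cycle_sample`s, or a single 101 x 24 feature matrix.
#' @param ... Unused.
#' @return Matrix (n x 101) of predicted envelopes; the sigmoid output layer
#'   bounds every value to (0, 1). Row order follows the input order.
#' @export
predict.gaitemg_estimator <- function(object, newdata, ...) {
  if (!object$trained) warning("predicting from an untrained estimator")
  if (is.list(newdata) && !is.null(newdata$X)) {
    bundle <- newdata
  } else if (is.matrix(newdata) && all(dim(newdata) == object$input_shape)) {
    fake <- list(structure(list(features = newdata,
                                targets = stats::setNames(list(NULL), "none")),
                           class = "gait_cycle_sample"))
    X <- matrix(as.vector(newdata), 1)
    A <- array(0, dim = c(1, object$input_shape[2], object$input_shape[1]))
    A[1, , ] <- t(newdata)
    bundle <- list(X = X, A = A)
  } else if (is.list(newdata) && length(newdata) &&
             inherits(newdata[[1]], "gait_cycle_sample")) {
    m <- newdata[[1]]$targets
    bundle <- samples_to_matrices(newdata, names(m)[1])
  } else {
    stop("predict: cannot interpret newdata")
  }
  w <- object$weights
  if (object$config$architecture == "fnn") {
    cpp_fnn_predict(w$W, w$b, bundle$X)
  } else {
    cpp_lstm_predict(w$Wx, w$Wh, w$b, w$Wd, w$bd, seq_cube(bundle$A),
                     object$config$lstm_head == "sequence")
  }
}

#' Save / load a trained estimator
#'
#' Checkpoints are written as an RDS file plus a human-readable YAML sidecar
#' holding the effective configuration.
#'
#' @param estimator A `gaitemg_estimator`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_estimator`: invisibly, the paths written; `load_estimator`:
#'   the estimator.
#' @export
save_estimator <- function(estimator, path) {
  saveRDS(estimator, path)
  side <- sub("\\.rds$", ".yml", path)
  yaml::write_yaml(c(unclass(estimator$config),
                     list(muscle = estimator$muscle,
                          trained = estimator$trained,
                          best_epoch = estimator$best_epoch)), side)
  invisible(c(path, side))
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) readRDS(path)

#' @export
print.gaitemg_estimator <- function(x, ...) {
  cat(sprintf("<gaitemg %s estimator: %d x %d hidden, %s, %d parameters%s>\n",
              toupper(x$config$architecture), x$config$hidden_layers,
              x$config$hidden_units,
              if (x$trained) "trained" else "untrained",
              count_parameters(x),
              if (!is.null(x$muscle)) paste0(", muscle ", x$muscle) else ""))
  invisible(x)
}
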