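#' Model configuration
#'
#' Describes one convolutional-recurrent sequence labeler: a stack of 1-D
#' convolutions (kernel 3, stride 1, same padding, ReLU) whose filter counts
#' are the prefix 8, 16, 32, ... of doubling widths, followed by a recurrent
#' head (LSTM, BiLSTM, GRU or BiGRU) read out at every timestep through a
#' dense softmax layer over the four wave classes. The 13 members of the
#' tuning family are available through [enumerate_configs()].
#'
#' @param conv_layers Number of convolution layers (1-9); filter counts are
#'   `8 * 2^(0:(conv_layers-1))`.
#' @param head One of `"LSTM"`, `"BiLSTM"`, `"GRU"`, `"BiGRU"`.
#' @param head_units Recurrent units per direction.
#' @param model_id Optional id (1-13) recorded for provenance.
#' @param input_length Beat-window length (512).
#' @param n_classes Number of sample classes (4).
#' @return A `model_config` list.
#' @export
model_config <- function(conv_layers, head = c("BiLSTM", "LSTM", "GRU", "BiGRU"),
                         head_units = 64L, model_id = NA_integer_,
                         input_length = beat_window_length(), n_classes = 4L) {
  head <- match.arg(head)
  conv_layers <- as.integer(conv_layers)
  if (is.na(conv_layers) || conv_layers < 1L || conv_layers > 9L) {
    stop("conv_layers must be between 1 and 9", call. = FALSE)
  }
  structure(list(
    model_id = model_id,
    conv_filters = as.integer(8L * 2L^(seq_len(conv_layers) - 1L)),
    kernel_size = 3L, stride = 1L, activation = "ReLU",
    head = head, head_units = as.integer(head_units),
    n_classes = as.integer(n_classes),
    input_length = as.integer(input_length)),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config", if (!is.na(x$model_id)) paste0(" #", x$model_id), "> ",
      length(x$conv_filters), " conv layer(s) [",
      paste(x$conv_filters, collapse = ", "), "] x3 stride 1 + ReLU -> ",
      x$head, "(", x$head_units, ")/timestep -> dense(", x$n_classes,
      ") softmax\n", sep = "")
  invisible(x)
}

#' The 13 tuning-family configurations
#'
#' Models 1-4: 1-4 convolution layers with an LSTM head. Models 5-13: 1-9
#' convolution layers with a BiLSTM head. All share kernel 3, stride 1,
#' ReLU activations.
#'
#' @param head_units Recurrent units per direction for every config.
#' @return List of 13 [model_config()] objects.
#' @export
enumerate_configs <- function(head_units = 64L) {
  lapply(1:13, function(id) {
    if (id <= 4L) model_config(id, head = "LSTM", head_units = head_units,
                               model_id = id)
    else model_config(id - 4L, head = "BiLSTM", head_units = head_units,
                      model_id = id)
  })
}

#' Trainable parameter count of a configuration
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(config) {
  ins <- c(1L, config$conv_filters)
  conv <- sum(3L * ins[-length(ins)] * config$conv_filters +
                config$conv_filters)
  H <- config$head_units
  D <- config$conv_filters[length(config$conv_filters)]
  gates <- if (config$head %in% c("GRU", "BiGRU")) 3L else 4L
  per_dir <- D * gates * H + H * gates * H + gates * H
  ndir <- if (config$head %in% c("BiLSTM", "BiGRU")) 2L else 1L
  dense <- ndir * H * config$n_classes + config$n_classes
  as.integer(conv + ndir * per_dir + dense)
}

.glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.cfg_for_cpp <- function(config) {
  list(conv_filters = config$conv_filters, head = tolower(config$head),
       head_units = config$head_units, n_classes = config$n_classes)
}

#' Build an initialized network from a configuration
#'
#' Weights are Glorot-uniform; recurrent and dense biases start at zero
#' except the LSTM forget-gate bias, initialized to 1 (the standard trick
#' that keeps the memory cell open early in training and lets long-range
#' information survive). The current RNG state determines the draw, so call
#' `set.seed()` first for reproducibility.
#'
#' @param config A [model_config()].
#' @return An `ecg_model`: configuration plus a named parameter list.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  H <- config$head_units
  gates <- if (config$head %in% c("GRU", "BiGRU")) 3L else 4L
  params <- list()
  ins <- c(1L, config$conv_filters)
  for (l in seq_along(config$conv_filters)) {
    cin <- ins[l]; cout <- config$conv_filters[l]
    params[[paste0("conv", l, "_W")]] <- .glorot(3L * cin, cout)
    params[[paste0("conv", l, "_b")]] <- matrix(0, 1L, cout)
  }
  D <- config$conv_filters[length(config$conv_filters)]
  dirs <- if (config$head %in% c("BiLSTM", "BiGRU")) c("rnn_f", "rnn_b")
          else "rnn_f"
  for (d in dirs) {
    params[[paste0(d, "_Wx")]] <- .glorot(D, gates * H, D, H)
    params[[paste0(d, "_Wh")]] <- .glorot(H, gates * H, H, H)
    b <- matrix(0, 1L, gates * H)
    if (gates == 4L) b[1L, (H + 1L):(2L * H)] <- 1  # forget gate
    params[[paste0(d, "_b")]] <- b
  }
  ndir <- length(dirs)
  params[["out_W"]] <- .glorot(ndir * H, config$n_classes)
  params[["out_b"]] <- matrix(0, 1L, config$n_classes)
  structure(list(config = config, params = params, trained = FALSE,
                 train_config = NULL, history = NULL),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  print(x$config)
  cat("  parameters: ", format(n_parameters(x$config), big.mark = ","),
      if (x$trained) "  (trained)" else "  (untrained)", "\n", sep = "")
  invisible(x)
}

#' Per-sample class probabilities for one beat window
#'
#' @param model An `ecg_model`.
#' @param signal Numeric vector of length `input_length`.
#' @return Matrix `input_length` x 4 of class probabilities (rows sum to 1).
#' @export
predict_probs <- function(model, signal) {
  stopifnot(inherits(model, "ecg_model"))
  if (length(signal) != model$config$input_length) {
    stop("input length ", length(signal), " != expected ",
         model$config$input_length, call. = FALSE)
  }
  .nn_forward_cpp(model$params, as.numeric(signal),
                  .cfg_for_cpp(model$config))
}

#' Predict a label stream for one beat window
#'
#' Per-sample argmax of the class probabilities; exact ties resolve to the
#' lower class index.
#'
#' @param model An `ecg_model`.
#' @param beat Either a numeric signal vector of length `input_length` or a
#'   one-row beat-window tibble (its `signal` column is used).
#' @return Integer label stream (values 0-3).
#' @export
predict_labels <- function(model, beat) {
  sig <- if (is.numeric(beat)) beat else beat$signal[[1L]]
  p <- predict_probs(model, sig)
  max.col(p, ties.method = "first") - 1L
}

#' @rdname predict_labels
#' @param object,newdata,type,... standard predict arguments; `newdata` is a
#'   beat-window tibble, `type` is `"class"` or `"prob"`.
#' @export
predict.ecg_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  sigs <- if (is.numeric(newdata)) list(newdata) else newdata$signal
  out <- lapply(sigs, function(s) {
    if (type == "prob") predict_probs(object, s)
    else predict_labels(object, s)
  })
  if (length(out) == 1L) out[[1L]] else out
}
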