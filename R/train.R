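#' Training configuration
#'
#' Defaults follow the reference training recipe: 300 epochs, batch size 8,
#' Adam at learning rate 1e-5, categorical cross-entropy computed over
#' non-padded samples only. Desk-scale experiments typically shrink epochs
#' and raise the learning rate.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Sequences per gradient step.
#' @param learning_rate Adam step size.
#' @param clip_norm Global gradient-norm ceiling (the usual guard against
#'   exploding recurrent gradients); `Inf` disables clipping.
#' @param seed Seed controlling weight initialization and shuffling.
#' @return A `train_config` list (loss is fixed to categorical
#'   cross-entropy, optimizer to Adam).
#' @export
train_config <- function(epochs = 300L, batch_size = 8L,
                         learning_rate = 1e-5, clip_norm = 1.0, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 loss = "categorical cross-entropy", optimizer = "Adam",
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack beat windows into T x N matrices for the C++ core
.beats_to_arrays <- function(beats) {
  len <- beat_window_length()
  n <- nrow(beats)
  X <- matrix(0, len, n)
  Y <- matrix(0L, len, n)
  M <- matrix(0L, len, n)
  for (i in seq_len(n)) {
    X[, i] <- beats$signal[[i]]
    Y[, i] <- beats$labels[[i]]
    M[seq_len(beats$valid_length[i]), i] <- 1L
  }
  list(X = X, Y = Y, M = M)
}

# loss/accuracy over a beat set without gradients, in memory-bounded chunks
.eval_arrays <- function(params, arr, cfg, chunk = 64L) {
  n <- ncol(arr$X)
  loss_sum <- 0; correct <- 0L; total <- 0L
  for (s in seq.int(1L, n, by = chunk)) {
    j <- s:min(n, s + chunk - 1L)
    r <- .nn_batch_cpp(params, arr$X[, j, drop = FALSE],
                       arr$Y[, j, drop = FALSE], arr$M[, j, drop = FALSE],
                       cfg, FALSE)
    loss_sum <- loss_sum + r$loss * r$n
    correct <- correct + r$correct
    total <- total + r$n
  }
  list(loss = loss_sum / total, acc = correct / total)
}

#' Train a sequence-labeling model
#'
#' Minimizes masked categorical cross-entropy with Adam. Padded positions
#' (at or beyond each beat's `valid_length`) contribute neither to the loss
#' nor to the reported accuracies. With a fixed seed the loss trajectory is
#' reproducible.
#'
#' @param config A [model_config()] (a fresh network is initialized) or an
#'   existing `ecg_model` to continue training.
#' @param train_beats Beat-window tibble (non-empty).
#' @param val_beats Optional beat-window tibble scored after every epoch.
#' @param tc A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A trained `ecg_model` whose `history` is a tibble with one row
#'   per epoch (`epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_model <- function(config, train_beats, val_beats = NULL,
                        tc = train_config(), verbose = FALSE) {
  if (is.null(train_beats) || nrow(train_beats) == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(tc$seed)
  model <- if (inherits(config, "ecg_model")) config else
    build_network(config)
  cfg <- .cfg_for_cpp(model$config)
  params <- model$params
  arr <- .beats_to_arrays(train_beats)
  varr <- if (!is.null(val_beats) && nrow(val_beats)) .beats_to_arrays(val_beats)
  n <- ncol(arr$X)

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  hist <- vector("list", tc$epochs)

  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
    for (s in seq.int(1L, n, by = tc$batch_size)) {
      j <- ord[s:min(n, s + tc$batch_size - 1L)]
      r <- .nn_batch_cpp(params, arr$X[, j, drop = FALSE],
                         arr$Y[, j, drop = FALSE], arr$M[, j, drop = FALSE],
                         cfg, TRUE)
      if (!is.finite(r$loss)) {
        stop("NaN/Inf loss at epoch ", ep, ", step ", step + 1L,
             "; lower the learning rate", call. = FALSE)
      }
      step <- step + 1L
      gnorm <- sqrt(sum(vapply(r$grads, function(g) sum(g^2), numeric(1))))
      scale <- if (is.finite(tc$clip_norm) && gnorm > tc$clip_norm)
        tc$clip_norm / gnorm else 1
      for (k in names(params)) {
        g <- r$grads[[k]] * scale
        adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * g
        adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * g^2
        mh <- adam_m[[k]] / (1 - b1^step)
        vh <- adam_v[[k]] / (1 - b2^step)
        params[[k]] <- params[[k]] - tc$learning_rate * mh / (sqrt(vh) + eps)
      }
      ep_loss <- ep_loss + r$loss * r$n
      ep_correct <- ep_correct + r$correct
      ep_n <- ep_n + r$n
    }
    v <- if (!is.null(varr)) .eval_arrays(params, varr, cfg)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / ep_n, accuracy = ep_correct / ep_n,
      val_loss = if (is.null(varr)) NA_real_ else v$loss,
      val_accuracy = if (is.null(varr)) NA_real_ else v$acc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", ep,
                      hist[[ep]]$loss, hist[[ep]]$accuracy,
                      if (is.null(varr)) "" else
                        sprintf("  val_loss %.4f  val_acc %.4f",
                                v$loss, v$acc)))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$train_config <- tc
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Per-sample confusion matrix
#'
#' Entry (i, j) counts unmasked samples whose true class is i and predicted
#' class is j (classes 0-3).
#'
#' @param true,predicted Integer label streams (vectors, or lists of
#'   vectors which are concatenated).
#' @param mask Optional 0/1 mask (same shape); padded samples are 0 and are
#'   excluded. Default: all samples count.
#' @return 4x4 integer matrix with dimnames iso/P/QRS/T.
#' @export
confusion_matrix <- function(true, predicted, mask = NULL) {
  tv <- if (is.list(true)) unlist(true) else true
  pv <- if (is.list(predicted)) unlist(predicted) else predicted
  if (length(tv) != length(pv)) {
    stop("true and predicted lengths differ", call. = FALSE)
  }
  if (!is.null(mask)) {
    mv <- if (is.list(mask)) unlist(mask) else mask
    if (length(mv) != length(tv)) stop("mask length differs", call. = FALSE)
    keep <- mv != 0L
    tv <- tv[keep]; pv <- pv[keep]
  }
  cm <- matrix(tabulate(tv * 4L + pv + 1L, nbins = 16L), 4L, 4L, byrow = TRUE)
  dimnames(cm) <- list(true = names(wave_classes()),
                       predicted = names(wave_classes()))
  cm
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest per class c: SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' PRE = TP/(TP+FP), ACC = (TP+TN)/N, F1 = 2*PRE*SEN/(PRE+SEN), all in
#' percent. Ratios with a zero denominator are reported as `NA` and
#' excluded from the unweighted macro means.
#'
#' @param confusion 4x4 non-negative matrix (rows = true).
#' @param scope Label recorded in the report (a lead name or `"all"`).
#' @return A `metrics_report`: list with `confusion`, `per_class` tibble,
#'   `macro` named vector, `scope`, `n_samples`.
#' @export
per_class_metrics <- function(confusion, scope = "all") {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(4L, 4L)))
  if (any(confusion < 0)) stop("confusion entries must be non-negative",
                               call. = FALSE)
  N <- sum(confusion)
  rows <- purrr::map_dfr(seq_len(4L), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- N - tp - fn - fp
    div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    sen <- div(tp, tp + fn)
    spe <- div(tn, tn + fp)
    pre <- div(tp, tp + fp)
    acc <- div(tp + tn, N)
    f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
      2 * pre * sen / (pre + sen)
    tibble::tibble(class = names(wave_classes())[c], acc = acc, sen = sen,
                   spe = spe, pre = pre, f1 = f1)
  })
  macro <- vapply(rows[, -1L], function(x) mean(x, na.rm = TRUE), numeric(1))
  structure(list(confusion = confusion, per_class = rows, macro = macro,
                 scope = scope, n_samples = N),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> scope ", x$scope, ", n = ", x$n_samples,
      " samples\n", sep = "")
  print(as.data.frame(x$per_class), digits = 4)
  cat("macro:", paste(names(x$macro),
                      sprintf("%.2f", x$macro), collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate a model on beat windows
#'
#' @param model Trained `ecg_model`.
#' @param beats Beat-window tibble.
#' @param scope Label for the report.
#' @return A `metrics_report` over all unmasked samples of `beats`.
#' @export
evaluate_model <- function(model, beats, scope = "all") {
  preds <- lapply(beats$signal, function(s) predict_labels(model, s))
  masks <- lapply(beats$valid_length, function(v) {
    m <- integer(beat_window_length()); m[seq_len(v)] <- 1L; m
  })
  cm <- confusion_matrix(beats$labels, preds, masks)
  per_class_metrics(cm, scope = scope)
}

#' Per-lead and pooled evaluation
#'
#' @param model Trained `ecg_model`.
#' @param beats Beat-window tibble carrying `lead`.
#' @return Named list of `metrics_report`s, one per lead present plus
#'   `"all"` (pooled).
#' @export
evaluate_per_lead <- function(model, beats) {
  leads <- intersect(ecg_leads(), unique(as.character(beats$lead)))
  reports <- lapply(leads, function(ld) {
    evaluate_model(model, beats[beats$lead == ld, ], scope = ld)
  })
  names(reports) <- leads
  reports[["all"]] <- evaluate_model(model, beats, scope = "all")
  structure(reports, class = "lead_metrics")
}

#' Compare recurrent heads on identical data
#'
#' Trains one model per head with the same convolution stack, data and seed,
#' and tabulates macro metrics on the evaluation set.
#'
#' @param heads Character vector from
#'   `c("GRU", "BiGRU", "LSTM", "BiLSTM")`.
#' @param train_beats,eval_beats Beat-window tibbles.
#' @param conv_layers Convolution depth shared by all heads.
#' @param head_units Units per direction.
#' @param tc A [train_config()] reused (same seed) for every head.
#' @return Tibble with one row per head: macro `acc`, `sen`, `spe`, `pre`,
#'   `f1` (percent), sorted by decreasing `f1`.
#' @export
compare_heads <- function(heads = c("GRU", "BiGRU", "LSTM", "BiLSTM"),
                          train_beats, eval_beats, conv_layers = 2L,
                          head_units = 16L, tc = train_config()) {
  stopifnot(all(heads %in% c("GRU", "BiGRU", "LSTM", "BiLSTM")))
  rows <- purrr::map_dfr(heads, function(h) {
    cfg <- model_config(conv_layers, head = h, head_units = head_units)
    m <- train_model(cfg, train_beats, tc = tc)
    rep <- evaluate_model(m, eval_beats, scope = h)
    tibble::as_tibble(c(list(head = h), as.list(rep$macro)))
  })
  dplyr::arrange(rows, dplyr::desc(.data$f1))
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ecg_model <- function(x, ...) {
  if (is.null(x$history)) tibble::tibble() else x$history
}

#' @export
glance.ecg_model <- function(x, ...) {
  last <- if (is.null(x$history)) tibble::tibble(loss = NA_real_,
                                                 accuracy = NA_real_) else
    x$history[nrow(x$history), c("loss", "accuracy", "val_loss",
                                 "val_accuracy")]
  dplyr::bind_cols(
    tibble::tibble(model_id = x$config$model_id,
                   head = x$config$head,
                   conv_layers = length(x$config$conv_filters),
                   n_parameters = n_parameters(x$config),
                   trained = x$trained),
    last)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(scope = x$scope), x$per_class)
}

#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(scope = x$scope,
                                  n_samples = x$n_samples),
                   tibble::as_tibble(as.list(x$macro)))
}

#' @export
tidy.lead_metrics <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @export
glance.lead_metrics <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}
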