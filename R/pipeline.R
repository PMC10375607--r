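#' Default pipeline configuration
#'
#' A desk-scale synthetic end-to-end demonstration: generate a small WFDB
#' corpus, denoise it, segment it, split it patient-wise, train a reduced
#' model briefly and delineate the test set.
#'
#' @param out_dir Artifact directory.
#' @param seed Master seed for every stochastic stage.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("ecgdelin_run_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(source = "synthetic", n_records = 8L, noise_sigma = 0.03,
                 wander_amp = 0.05),
    denoise = list(enabled = TRUE, wavelet = "bior6.8", level = 8L),
    split = list(mode = "patient_based",
                 patient_ranges = list(train = c(1L, 6L),
                                       validation = c(7L, 7L),
                                       test = c(8L, 8L))),
    model = list(conv_layers = 2L, head = "BiLSTM", head_units = 16L),
    train = list(epochs = 8L, batch_size = 8L, learning_rate = 1e-3),
    delineate = list(min_run = 10L, tolerance = 75L)
  )
}

.require_field <- function(config, path) {
  node <- config
  for (p in path) {
    if (is.null(node[[p]])) {
      stop("config error: missing field '", paste(path, collapse = "."),
           "'", call. = FALSE)
    }
    node <- node[[p]]
  }
  node
}

#' Run the end-to-end delineation pipeline
#'
#' Stages: acquire (synthesize or read WFDB), denoise, segment, split,
#' train, evaluate, delineate. Every stage's outputs land in
#' `config$out_dir`; `manifest.json` records every setting, the seed and the
#' stage list.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one.
#' @return Invisibly, a list with the trained model, the metrics reports,
#'   the interval tables and all artifact paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: not a list", call. = FALSE)
  seed <- .require_field(config, "seed")
  out_dir <- .require_field(config, "out_dir")
  source <- .require_field(config, c("input", "source"))
  if (!source %in% c("synthetic", "wfdb")) {
    stop("config error: input.source must be 'synthetic' or 'wfdb'",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  stages <- character(0)

  # -- stage 1: acquire -------------------------------------------------------
  if (source == "synthetic") {
    wfdb_dir <- file.path(out_dir, "wfdb")
    n_rec <- .require_field(config, c("input", "n_records"))
    scfg <- synth_config(
      noise = list(white_sd = config$input$noise_sigma %||% 0.05,
                   wander_amp = config$input$wander_amp %||% 0.05,
                   wander_freq = 0.3),
      seed = seed)
    synth_dataset(wfdb_dir, n_rec, scfg, seed = seed)
    stages <- c(stages, "synth")
    log_line("synth", paste(n_rec, "records ->", wfdb_dir))
  } else {
    wfdb_dir <- .require_field(config, c("input", "dir"))
    stages <- c(stages, "load")
    log_line("load", wfdb_dir)
  }
  ids <- sort(as.integer(sub("\\.hea$", "",
                             basename(list.files(wfdb_dir, "\\.hea$")))))
  records <- lapply(as.character(ids), function(id) read_record(wfdb_dir, id))
  triplets <- lapply(as.character(ids),
                     function(id) read_record_triplets(wfdb_dir, id))

  # -- stage 2: denoise -------------------------------------------------------
  if (isTRUE(config$denoise$enabled %||% TRUE)) {
    dcfg <- denoise_config(config$denoise$wavelet %||% "bior6.8",
                           config$denoise$level %||% 8L)
    snr_before <- records
    records <- lapply(records, denoise_record, config = dcfg)
    snr <- mean(unlist(purrr::map2(snr_before, records, function(a, b) {
      vapply(seq_len(12L), function(i) snr_db(a$signals[, i], b$signals[, i]),
             numeric(1))
    })))
    stages <- c(stages, "denoise")
    log_line("denoise", sprintf("%s level %d, mean retained-SNR %.2f dB",
                                dcfg$wavelet, dcfg$level, snr))
  } else stages <- c(stages, "denoise")

  # -- stage 3: segment -------------------------------------------------------
  beats <- purrr::map2_dfr(records, triplets, segment_record)
  stages <- c(stages, "segment")
  log_line("segment", paste(nrow(beats), "beat windows"))

  # -- stage 4: split ---------------------------------------------------------
  smode <- config$split$mode %||% "patient_based"
  spec <- if (smode == "patient_based") {
    pr <- .require_field(config, c("split", "patient_ranges"))
    split_spec(mode = "patient_based",
               patient_ranges = lapply(pr, function(r) r[1L]:r[2L]),
               seed = seed)
  } else {
    split_spec(mode = "beat_based",
               fractions = unlist(config$split$fractions %||%
                                    c(0.80, 0.12, 0.08)),
               seed = seed)
  }
  split <- make_split(beats, spec)
  stages <- c(stages, "split")
  log_line("split", sprintf("%s: train %d / validation %d / test %d", smode,
                            nrow(split$train), nrow(split$validation),
                            nrow(split$test)))

  # -- stage 5: train ---------------------------------------------------------
  mcfg <- if (!is.null(config$model$config_id)) {
    enumerate_configs(config$model$head_units %||% 64L)[[config$model$config_id]]
  } else {
    model_config(config$model$conv_layers %||% 2L,
                 head = config$model$head %||% "BiLSTM",
                 head_units = config$model$head_units %||% 16L)
  }
  tc <- train_config(epochs = config$train$epochs %||% 8L,
                     batch_size = config$train$batch_size %||% 8L,
                     learning_rate = config$train$learning_rate %||% 1e-3,
                     seed = seed)
  model <- train_model(mcfg, split$train, split$validation, tc)
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  stages <- c(stages, "train")
  log_line("train", sprintf("final loss %.4f acc %.4f",
                            model$history$loss[tc$epochs],
                            model$history$accuracy[tc$epochs]))

  # -- stage 6: evaluate ------------------------------------------------------
  eval_set <- if (nrow(split$test)) split$test else split$validation
  reports <- evaluate_per_lead(model, eval_set)
  utils::write.csv(tidy(reports), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(reports$all$confusion),
                   file.path(out_dir, "confusion_all.csv"))
  stages <- c(stages, "evaluate")
  log_line("evaluate", sprintf("test macro F1 %.2f%%", reports$all$macro["f1"]))

  # -- stage 7: delineate -----------------------------------------------------
  min_run <- config$delineate$min_run %||% 10L
  tol <- config$delineate$tolerance %||% 75L
  per_beat <- purrr::map(seq_len(nrow(eval_set)), function(i) {
    b <- eval_set[i, ]
    pred <- labels_to_intervals(predict_labels(model, b), min_run)
    tru <- labels_to_intervals(b$labels[[1L]], min_run = 1L)
    iv <- dplyr::bind_rows(
      dplyr::mutate(tru, source = "ground_truth"),
      dplyr::mutate(pred, source = "predicted")) |>
      dplyr::mutate(record_id = b$record_id, lead = b$lead,
                    beat_index = b$beat_index, .before = 1L)
    list(iv = iv, match = match_intervals(pred, tru, tolerance = tol))
  })
  iv_rows <- purrr::map_dfr(per_beat, "iv")
  utils::write.csv(iv_rows, file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)
  match <- list(
    summary = purrr::map_dfr(per_beat, function(p) p$match$summary) |>
      dplyr::group_by(.data$wave_type) |>
      dplyr::summarise(dplyr::across(c("matched", "missed", "spurious"), sum),
                       .groups = "drop"),
    errors = purrr::map_dfr(per_beat, function(p) p$match$errors))
  utils::write.csv(match$summary, file.path(out_dir, "match_summary.csv"),
                   row.names = FALSE)
  stages <- c(stages, "delineate")
  log_line("delineate", paste(sum(match$summary$matched), "waves matched"))

  manifest <- list(stages = stages, seed = seed, config = config,
                   n_beats = nrow(beats),
                   split_sizes = vapply(split, nrow, integer(1)),
                   macro_test = as.list(reports$all$macro))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, reports = reports, intervals = iv_rows,
                 match = match, split = split, beats = beats,
                 out_dir = out_dir, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
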