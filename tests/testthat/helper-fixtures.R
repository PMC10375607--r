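# Shared fixtures, generated once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

noise_free_config <- function(seed = 5L) {
  synth_config(noise = list(white_sd = 0, wander_amp = 0, wander_freq = 0.3),
               seed = seed)
}

# ~250 noise-free beats pooled over 12 leads of two records
noise_free_beats <- function() {
  if (is.null(.fixtures$beats)) {
    .fixtures$beats <- dplyr::bind_rows(lapply(1:2, function(i) {
      cfg <- noise_free_config(seed = i + 10L)
      sr <- synth_record(cfg, as.character(i))
      segment_record(sr$record, sr$triplets)
    }))
  }
  .fixtures$beats
}

# a small noisy WFDB corpus on disk, plus the generating configuration
synth_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    dir <- file.path(tempdir(), "ecgdelin-corpus")
    cfg <- synth_config(seed = 3L)
    manifest <- synth_dataset(dir, 3L, cfg)
    .fixtures$corpus <- list(dir = dir, config = cfg, manifest = manifest)
  }
  .fixtures$corpus
}

# the reduced synthetic-recovery experiment: 2 conv layers, 16 BiLSTM units,
# 200 noise-free training beats, 20 epochs
trained_reduced_model <- function() {
  if (is.null(.fixtures$trained)) {
    beats <- noise_free_beats()
    set.seed(1)
    idx <- sample(nrow(beats))
    train <- beats[idx[1:200], ]
    val <- beats[idx[201:240], ]
    tc <- train_config(epochs = 20L, batch_size = 8L, learning_rate = 1e-3,
                       seed = 2L)
    model <- train_model(model_config(2L, head = "BiLSTM", head_units = 16L),
                         train, val, tc)
    .fixtures$trained <- list(model = model, train = train, val = val)
  }
  .fixtures$trained
}

random_triplets <- function(n, max_sample = 200L) {
  starts <- sort(sample.int(max_sample - 10L, n))
  len <- sample(1:8, n, replace = TRUE)
  tibble::tibble(
    wave_type = factor(sample(c("P", "QRS", "T"), n, replace = TRUE),
                       levels = c("P", "QRS", "T")),
    onset = starts,
    peak = pmin(starts + len %/% 2L, max_sample - 1L),
    offset = pmin(starts + len, max_sample - 1L))
}
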