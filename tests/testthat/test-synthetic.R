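test_that("the clean beat equals its closed form at the P peak", {
  cfg <- synth_config()
  beat <- gaussian_beat(cfg)
  p <- beat$triplets[beat$triplets$wave_type == "P", ]
  a_p <- cfg$wave_params$P[["a"]]
  expect_lt(abs(beat$signal[p$peak + 1L] - a_p), 1e-6)
  expect_true(all(beat$triplets$onset <= beat$triplets$peak &
                    beat$triplets$peak <= beat$triplets$offset))
})

test_that("zero amplitudes give a flat beat with well-formed triplets", {
  cfg <- synth_config()
  for (w in names(cfg$wave_params)) cfg$wave_params[[w]][["a"]] <- 0
  beat <- gaussian_beat(cfg)
  expect_equal(beat$signal, numeric(length(beat$signal)))
  expect_equal(nrow(beat$triplets), 3L)
})

test_that("generation is deterministic in the seed", {
  a <- synth_record(synth_config(seed = 123L), "a")
  b <- synth_record(synth_config(seed = 123L), "a")
  expect_identical(a$record$signals, b$record$signals)
  expect_identical(a$triplets, b$triplets)
})

test_that("a 60 bpm 10 s record carries 10 +/- 1 beats per lead", {
  sr <- synth_record(synth_config(heart_rate_bpm = 60, seed = 2L))
  n_beats <- sum(sr$triplets$lead == "II" & sr$triplets$wave_type == "P")
  expect_gte(n_beats, 9L)
  expect_lte(n_beats, 11L)
})

test_that("aVR is the inverted, scaled projection of the common source", {
  cfg <- noise_free_config(4L)
  sr <- synth_record(cfg)
  r_peak <- sr$triplets$peak[sr$triplets$lead == "II" &
                               sr$triplets$wave_type == "QRS"][1L]
  ratio <- unname(sr$record$signals[r_peak + 1L, "aVR"] /
                    sr$record$signals[r_peak + 1L, "II"])
  expect_equal(ratio, cfg$lead_profile[["aVR"]] / cfg$lead_profile[["II"]],
               tolerance = 1e-10)
  expect_lt(sr$record$signals[r_peak + 1L, "aVR"], 0)
})

test_that("a noise-free record has infinite SNR against its clean source", {
  sr <- synth_record(noise_free_config(8L))
  expect_identical(snr_db(sr$clean[, "II"], sr$record$signals[, "II"]), Inf)
})

test_that("triplet-derived label streams reproduce the generator's own mask", {
  sr <- synth_record(noise_free_config(6L))
  for (ld in c("II", "aVR", "V5")) {
    ls <- build_label_stream(sr$triplets[sr$triplets$lead == ld, ],
                             sr$record$n_samples)
    expect_identical(ls, sr$label_mask)
  }
})

test_that("overlapping ground-truth intervals are rejected at construction", {
  expect_error(
    synth_config(wave_params = list(
      P = c(a = 0.15, mu = -0.08, sigma = 0.02),   # P runs into the QRS
      Q = c(a = -0.1, mu = -0.035, sigma = 0.008),
      R = c(a = 1, mu = 0, sigma = 0.012),
      S = c(a = -0.15, mu = 0.035, sigma = 0.008),
      T = c(a = 0.3, mu = 0.3, sigma = 0.05))),
    "overlapping")
})

test_that("a written corpus reads back with identical annotations", {
  corp <- synth_corpus()
  expect_equal(nrow(corp$manifest), 3L)
  for (id in corp$manifest$record_id) {
    expect_true(file.exists(file.path(corp$dir, paste0(id, ".hea"))))
    anns <- list.files(corp$dir, paste0("^", id, "\\.[a-z0-9]+$"))
    expect_length(setdiff(paste0(id, ".", tolower(ecg_leads())),
                          c(anns, paste0(id, ".dat"), paste0(id, ".hea"))), 0L)
  }
  # triplets round-trip exactly
  cfg1 <- corp$config
  cfg1$seed <- corp$manifest$seed[1L]
  sr1 <- synth_record(cfg1, "1")
  back <- read_record_triplets(corp$dir, "1")
  expect_equal(back$onset, sr1$triplets$onset)
  expect_equal(back$peak, sr1$triplets$peak)
  expect_equal(back$offset, sr1$triplets$offset)
  expect_equal(as.character(back$wave_type), as.character(sr1$triplets$wave_type))
})

test_that("segmentation of a tiled record yields one beat per onset pair", {
  corp <- synth_corpus()
  rec <- read_record(corp$dir, "2")
  tr <- read_record_triplets(corp$dir, "2")
  beats <- segment_record(rec, tr)
  for (ld in ecg_leads()) {
    n_onsets <- sum(tr$lead == ld & tr$wave_type == "P")
    expect_equal(sum(beats$lead == ld), n_onsets - 1L)
  }
})
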