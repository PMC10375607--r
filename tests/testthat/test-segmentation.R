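mk_triplets <- function(...) {
  rows <- list(...)
  tibble::tibble(
    wave_type = factor(vapply(rows, `[[`, character(1), 1L),
                       levels = c("P", "QRS", "T")),
    onset = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    peak = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    offset = vapply(rows, function(r) as.integer(r[[4]]), integer(1)))
}

test_that("beats span consecutive P onsets and need a complete QRS", {
  tr <- mk_triplets(c("P", 100, 110, 120), c("QRS", 200, 210, 220),
                    c("T", 300, 320, 340), c("P", 550, 560, 570))
  b <- locate_beat_boundaries(tr)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 550L)
  # a single P wave yields nothing (no second onset)
  expect_equal(nrow(locate_beat_boundaries(mk_triplets(c("P", 100, 110, 120)))),
               0L)
  # a span without a QRS inside is excluded and tallied
  no_qrs <- mk_triplets(c("P", 100, 110, 120), c("P", 500, 510, 520),
                        c("QRS", 600, 610, 620), c("P", 900, 910, 920))
  b2 <- locate_beat_boundaries(no_qrs)
  expect_equal(b2$start, 500L)
  expect_equal(attr(b2, "excluded"), 1L)
})

test_that("short beats are zero-padded to 512 and long ones clipped", {
  set.seed(12)
  n <- 2000L
  rec <- ecg_record("pad", 500, matrix(rnorm(n * 12L), n, 12L))
  tr <- mk_triplets(c("P", 100, 110, 120), c("QRS", 200, 210, 220),
                    c("P", 500, 510, 520), c("QRS", 600, 610, 620),
                    c("P", 1100, 1110, 1120))
  w <- extract_beat_windows(rec, tr, "II")
  expect_equal(nrow(w), 2L)
  # beat 1: span 400 -> padded
  expect_equal(w$valid_length[1L], 400L)
  expect_equal(w$signal[[1L]][401:512], numeric(112))
  expect_equal(w$labels[[1L]][401:512], integer(112))
  expect_equal(w$signal[[1L]][1:400], rec$signals[101:500, "II"])
  # beat 2: span 600 -> clipped at 512, labels clipped identically
  expect_equal(w$valid_length[2L], 512L)
  expect_equal(w$signal[[2L]], rec$signals[501:1012, "II"])
  expect_equal(attr(w, "clipped"), 1L)
  # labels re-based to window coordinates
  expect_equal(which(w$labels[[1L]] == wave_classes()[["QRS"]]) - 1L, 100:120)
})

test_that("a span of exactly 512 samples passes through unchanged", {
  set.seed(13)
  rec <- ecg_record("x", 500, matrix(rnorm(1500 * 12L), 1500L, 12L))
  tr <- mk_triplets(c("P", 100, 105, 110), c("QRS", 150, 160, 170),
                    c("P", 612, 620, 630), c("QRS", 700, 710, 720),
                    c("P", 1200, 1210, 1220))
  w <- extract_beat_windows(rec, tr, "V1")
  expect_equal(w$valid_length[1L], 512L)
  expect_equal(w$signal[[1L]], rec$signals[101:612, "V1"])
})

test_that("both split modes conserve beats and keep collections disjoint", {
  beats <- noise_free_beats()
  key <- function(b) paste(b$record_id, b$lead, b$beat_index)

  pb <- make_split(beats, split_spec(mode = "patient_based",
                                     patient_ranges = list(train = 1L,
                                                           validation = 2L,
                                                           test = integer(0))))
  expect_equal(sum(vapply(pb, nrow, integer(1))), nrow(beats))
  expect_length(intersect(unique(pb$train$record_id),
                          unique(pb$validation$record_id)), 0L)

  bb <- make_split(beats, split_spec(mode = "beat_based", seed = 11L))
  expect_equal(sum(vapply(bb, nrow, integer(1))), nrow(beats))
  allk <- c(key(bb$train), key(bb$validation), key(bb$test))
  expect_equal(sort(allk), sort(key(beats)))  # union = input, no duplicates
})

test_that("beat-based splitting is deterministic in the seed and honors fractions", {
  beats <- noise_free_beats()
  s1 <- make_split(beats, split_spec(mode = "beat_based", seed = 42L))
  s2 <- make_split(beats, split_spec(mode = "beat_based", seed = 42L))
  expect_identical(s1, s2)
  all_train <- make_split(beats, split_spec(mode = "beat_based",
                                            fractions = c(1, 0, 0)))
  expect_equal(nrow(all_train$train), nrow(beats))
  expect_equal(nrow(all_train$test), 0L)
  # per-lead 80/12/8 partition, floor rule
  n_lead <- sum(beats$lead == "II")
  s3 <- make_split(beats, split_spec(mode = "beat_based", seed = 1L))
  expect_equal(sum(s3$train$lead == "II"), floor(0.80 * n_lead))
})

test_that("every emitted window zeroes labels beyond valid_length", {
  beats <- noise_free_beats()
  short <- beats[beats$valid_length < 512L, ]
  expect_gt(nrow(short), 0L)
  ok <- vapply(seq_len(nrow(short)), function(i) {
    all(short$labels[[i]][(short$valid_length[i] + 1L):512L] == 0L)
  }, logical(1))
  expect_true(all(ok))
})

test_that("misconfigured splits raise parameter errors", {
  expect_error(split_spec(mode = "beat_based", fractions = c(0.5, 0.1, 0.1)),
               "summing to 1")
  expect_error(split_spec(patient_ranges = list(1:5, 5:6, 7L)), "disjoint")
  beats <- noise_free_beats()
  expect_error(make_split(beats, split_spec(patient_ranges =
    list(train = 1L, validation = integer(0), test = integer(0)))),
    "not covered")
})
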