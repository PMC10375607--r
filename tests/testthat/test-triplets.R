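ann <- function(...) {
  x <- list(...)
  tibble::tibble(symbol = vapply(x, function(p) p[[1]], character(1)),
                 sample = vapply(x, function(p) as.integer(p[[2]]), integer(1)))
}

test_that("complete runs pair into typed triplets", {
  tr <- pair_wave_triplets(ann(list("(", 10), list("p", 15), list(")", 20)))
  expect_equal(nrow(tr), 1L)
  expect_equal(as.character(tr$wave_type), "P")
  expect_equal(c(tr$onset, tr$peak, tr$offset), c(10L, 15L, 20L))
  expect_equal(attr(tr, "excluded"), 0L)

  tr3 <- pair_wave_triplets(ann(
    list("(", 10), list("p", 15), list(")", 20),
    list("(", 30), list("N", 35), list(")", 40),
    list("(", 50), list("t", 60), list(")", 70)))
  expect_equal(as.character(tr3$wave_type), c("P", "QRS", "T"))
  expect_true(all(tr3$onset <= tr3$peak & tr3$peak <= tr3$offset))
})

test_that("incomplete runs are dropped and tallied, not repaired", {
  # missing '('
  tr <- pair_wave_triplets(ann(list("p", 15), list(")", 20)))
  expect_equal(nrow(tr), 0L)
  expect_equal(attr(tr, "excluded"), 1L)
  # two consecutive peaks with no boundary between them: both dropped
  tr2 <- pair_wave_triplets(ann(list("(", 10), list("p", 15), list("N", 18),
                                list(")", 25)))
  expect_equal(nrow(tr2), 0L)
  expect_equal(attr(tr2, "excluded"), 2L)
  # trailing unclosed run
  tr3 <- pair_wave_triplets(ann(list("(", 10), list("p", 15)))
  expect_equal(nrow(tr3), 0L)
  expect_equal(attr(tr3, "excluded"), 1L)
})

test_that("unknown symbols raise a format error naming symbol and index", {
  expect_error(pair_wave_triplets(ann(list("(", 10), list("x", 15))),
               "'x' at sample 15")
})

test_that("parsing is order-insensitive after sorting", {
  a <- ann(list("(", 10), list("p", 15), list(")", 20),
           list("(", 30), list("N", 35), list(")", 40))
  set.seed(9)
  shuffled <- a[sample(nrow(a)), ]
  expect_equal(pair_wave_triplets(shuffled), pair_wave_triplets(a),
               ignore_attr = TRUE)
})

test_that("label streams use closed intervals and QRS > T > P precedence", {
  tr <- tibble::tibble(wave_type = factor("P", levels = c("P", "QRS", "T")),
                       onset = 10L, peak = 15L, offset = 20L)
  ls <- build_label_stream(tr, 30L)
  expect_equal(which(ls == 1L) - 1L, 10:20)
  expect_equal(sum(ls != 0L), 11L)

  expect_equal(build_label_stream(tr[0, ], 512L), integer(512))

  over <- tibble::tibble(
    wave_type = factor(c("T", "P"), levels = c("P", "QRS", "T")),
    onset = c(100L, 145L), peak = c(120L, 150L), offset = c(150L, 160L))
  ls2 <- build_label_stream(over, 200L)
  expect_equal(unique(ls2[146:151]), wave_classes()[["T"]])   # samples 145..150
  expect_equal(unique(ls2[152:161]), wave_classes()[["P"]])   # samples 151..160
})

test_that("out-of-range triplets are rejected with the triplet named", {
  tr <- tibble::tibble(wave_type = factor("QRS", levels = c("P", "QRS", "T")),
                       onset = 500L, peak = 505L, offset = 520L)
  expect_error(build_label_stream(tr, 512L), "QRS \\[500, 520\\]")
})

test_that("labeled-sample count equals the union of closed intervals", {
  # brute-force membership oracle on random small inputs
  set.seed(4)
  for (rep in 1:25) {
    tr <- random_triplets(sample(1:6, 1))
    n <- 200L
    ls <- build_label_stream(tr, n)
    member <- vapply(0:(n - 1L), function(s) {
      any(tr$onset <= s & s <= tr$offset)
    }, logical(1))
    expect_equal(sum(ls != 0L), sum(member))
  }
})

test_that("a full synthetic corpus parse recovers every annotated wave", {
  corp <- synth_corpus()
  total <- 0L
  for (id in corp$manifest$record_id) {
    tr <- read_record_triplets(corp$dir, id)
    expect_equal(attr(tr, "excluded"), 0L)
    total <- total + nrow(tr)
  }
  # ground truth: 3 waves per beat per lead
  expect_equal(total, sum(corp$manifest$n_beats) * 3L * 12L)
})
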