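test_that("confusion_matrix matches a per-sample counting oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 1000L
    tv <- sample(0:3, n, replace = TRUE)
    pv <- sample(0:3, n, replace = TRUE)
    mk <- rbinom(n, 1L, 0.85)
    cm <- confusion_matrix(tv, pv, mk)
    oracle <- matrix(0L, 4L, 4L)
    for (i in seq_len(n)) {
      if (mk[i] == 1L) {
        oracle[tv[i] + 1L, pv[i] + 1L] <- oracle[tv[i] + 1L, pv[i] + 1L] + 1L
      }
    }
    expect_equal(unname(cm), oracle)
    expect_equal(sum(cm), sum(mk))  # conservation over unmasked samples
  }
})

test_that("confusion_matrix handles degenerate and invalid input", {
  expect_equal(diag(confusion_matrix(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               c(iso = 1L, P = 1L, QRS = 1L, T = 1L))
  cm <- confusion_matrix(rep(1L, 7L), rep(3L, 7L))
  expect_equal(cm["P", "T"], 7L)
  expect_equal(sum(cm), 7L)
  expect_error(confusion_matrix(1:3, 1:4), "lengths differ")
})

test_that("per-class metrics match the one-vs-rest formulas", {
  # 2-class case embedded in the 4x4 layout, hand-computed
  cm <- matrix(0L, 4L, 4L)
  cm[1:2, 1:2] <- matrix(c(50L, 10L, 10L, 30L), 2L, byrow = TRUE)
  rep <- per_class_metrics(cm)
  c0 <- rep$per_class[1L, ]
  expect_equal(c0$sen, 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(c0$pre, 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(c0$spe, 100 * 30 / 40, tolerance = 1e-10)
  expect_equal(c0$acc, 80, tolerance = 1e-10)
  expect_equal(c0$f1, 100 * 50 / 60, tolerance = 1e-10)

  perfect <- per_class_metrics(diag(c(5L, 5L, 5L, 5L)))
  expect_true(all(abs(as.matrix(perfect$per_class[, -1L]) - 100) < 1e-10))

  # class with zero true samples: SEN undefined, macro over the rest
  expect_true(is.na(rep$per_class$sen[3L]))
  expect_equal(rep$macro[["sen"]],
               mean(rep$per_class$sen, na.rm = TRUE))
  expect_error(per_class_metrics(matrix(-1, 4, 4)), "non-negative")
})

test_that("metrics stay within bounds and F1 sits between PRE and SEN", {
  set.seed(15)
  for (rep_i in 1:100) {
    cm <- matrix(rpois(16L, 20L), 4L, 4L)
    r <- per_class_metrics(cm)
    vals <- as.matrix(r$per_class[, -1L])
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 100))
    with(r$per_class, {
      ok <- is.na(f1) | (f1 >= pmin(pre, sen) - 1e-9 &
                           f1 <= pmax(pre, sen) + 1e-9)
      expect_true(all(ok))
    })
    # independent recount of SEN from the raw matrix
    expect_equal(r$per_class$sen,
                 100 * diag(cm) / rowSums(cm), ignore_attr = TRUE)
  }
})

test_that("training logs one row per epoch and validates inputs", {
  beats <- noise_free_beats()[1:8, ]
  tc <- train_config(epochs = 1L, batch_size = 8L, learning_rate = 1e-4,
                     seed = 3L)
  m <- train_model(model_config(1L, head = "LSTM", head_units = 4L),
                   beats, tc = tc)
  expect_equal(nrow(m$history), 1L)
  expect_true(m$trained)
  expect_error(train_model(model_config(1L), beats[0, ], tc = tc),
               "empty")
})

test_that("the default training recipe mirrors the reference settings", {
  tc <- train_config()
  expect_equal(tc$epochs, 300L)
  expect_equal(tc$batch_size, 8L)
  expect_equal(tc$learning_rate, 1e-5)
  expect_equal(tc$loss, "categorical cross-entropy")
})

test_that("training is reproducible for a fixed seed", {
  beats <- noise_free_beats()[1:16, ]
  tc <- train_config(epochs = 2L, batch_size = 8L, learning_rate = 1e-3,
                     seed = 9L)
  m1 <- train_model(model_config(1L, head = "GRU", head_units = 4L),
                    beats, tc = tc)
  m2 <- train_model(model_config(1L, head = "GRU", head_units = 4L),
                    beats, tc = tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("evaluation on a single lead equals the pooled report", {
  fit <- trained_reduced_model()
  one_lead <- fit$val[fit$val$lead == fit$val$lead[1L], ]
  reps <- evaluate_per_lead(fit$model, one_lead)
  expect_named(reps, c(as.character(one_lead$lead[1L]), "all"))
  expect_equal(reps[[1L]]$confusion, reps$all$confusion)
  expect_equal(reps[[1L]]$per_class, reps$all$per_class)
})

test_that("padded samples are excluded from evaluation", {
  fit <- trained_reduced_model()
  rep <- evaluate_model(fit$model, fit$val)
  expect_equal(rep$n_samples, sum(fit$val$valid_length))
  expect_equal(sum(rep$confusion), sum(fit$val$valid_length))
})

test_that("compare_heads trains every requested head on identical data", {
  beats <- noise_free_beats()
  set.seed(2)
  idx <- sample(nrow(beats), 48L)
  tc <- train_config(epochs = 2L, batch_size = 8L, learning_rate = 1e-3,
                     seed = 5L)
  tbl <- compare_heads(c("GRU", "BiLSTM"), beats[idx[1:32], ],
                       beats[idx[33:48], ], conv_layers = 1L,
                       head_units = 4L, tc = tc)
  expect_equal(sort(tbl$head), c("BiLSTM", "GRU"))
  expect_true(all(tbl$f1 >= 0 & tbl$f1 <= 100))
  one <- compare_heads("LSTM", beats[idx[1:32], ], beats[idx[33:48], ],
                       conv_layers = 1L, head_units = 4L, tc = tc)
  expect_equal(nrow(one), 1L)
})

test_that("tidy and glance expose history and summary", {
  fit <- trained_reduced_model()
  h <- tidy(fit$model)
  expect_equal(nrow(h), 20L)
  expect_named(h, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))
  g <- glance(fit$model)
  expect_equal(g$head, "BiLSTM")
  expect_equal(g$conv_layers, 2L)
  rep <- evaluate_model(fit$model, fit$val)
  expect_named(glance(rep), c("scope", "n_samples", "acc", "sen", "spe",
                              "pre", "f1"))
})
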