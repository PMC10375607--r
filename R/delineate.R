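#' Convert a label stream to wave intervals
#'
#' Maximal constant non-zero runs shorter than `min_run` are first relabeled
#' to isoelectric (removing single-sample flicker), then every remaining
#' run becomes one interval. The default `min_run` of 10 samples is 20 ms
#' at 500 Hz.
#'
#' @param labels Integer label stream (values 0-3).
#' @param min_run Minimum run length kept, in samples (>= 1).
#' @return Tibble `wave_type` (factor P/QRS/T), `onset`, `offset`
#'   (0-based, closed intervals), ordered by onset.
#' @export
labels_to_intervals <- function(labels, min_run = 10L) {
  stopifnot(min_run >= 1L)
  r <- rle(as.integer(labels))
  r$values[r$values != 0L & r$lengths < min_run] <- 0L
  labels <- inverse.rle(r)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  cls <- names(wave_classes())[r$values[keep] + 1L]
  tibble::tibble(
    wave_type = factor(cls, levels = c("P", "QRS", "T")),
    onset = starts[keep] - 1L,
    offset = ends[keep] - 1L)
}

#' Match predicted wave intervals to ground truth
#'
#' Greedy one-to-one matching per wave type: candidate pairs are ranked by
#' overlap (in samples), and a pair is accepted when each partner is still
#' unmatched and the onset/offset discrepancies are both within `tolerance`
#' samples. Unmatched truth intervals are `missed`, unmatched predictions
#' `spurious`.
#'
#' @param predicted,truth Interval tibbles (`wave_type`, `onset`, `offset`),
#'   as from [labels_to_intervals()].
#' @param tolerance Maximum allowed boundary discrepancy in samples
#'   (default 75 = 150 ms at 500 Hz).
#' @param fs Sampling rate, used only to report errors in ms.
#' @return List with `summary` (tibble per wave type: `matched`, `missed`,
#'   `spurious`) and `errors` (tibble per matched pair: `wave_type`,
#'   `onset_error`, `offset_error` in samples and `onset_error_ms`,
#'   `offset_error_ms`).
#' @export
match_intervals <- function(predicted, truth, tolerance = 75L, fs = 500) {
  per_type <- function(wt) {
    p <- predicted[predicted$wave_type == wt, ]
    g <- truth[truth$wave_type == wt, ]
    np <- nrow(p); ng <- nrow(g)
    if (np == 0L || ng == 0L) {
      return(list(summary = tibble::tibble(wave_type = wt, matched = 0L,
                                           missed = ng, spurious = np),
                  errors = NULL))
    }
    ov <- matrix(0L, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      ov[i, j] <- max(0L, min(g$offset[i], p$offset[j]) -
                        max(g$onset[i], p$onset[j]) + 1L)
    }
    used_g <- logical(ng); used_p <- logical(np)
    pairs <- list()
    ord <- order(ov, decreasing = TRUE)
    for (k in ord) {
      if (ov[k] <= 0L) break
      i <- (k - 1L) %% ng + 1L
      j <- (k - 1L) %/% ng + 1L
      if (used_g[i] || used_p[j]) next
      if (abs(p$onset[j] - g$onset[i]) > tolerance ||
          abs(p$offset[j] - g$offset[i]) > tolerance) next
      used_g[i] <- TRUE; used_p[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        wave_type = wt,
        onset_error = p$onset[j] - g$onset[i],
        offset_error = p$offset[j] - g$offset[i])
    }
    list(summary = tibble::tibble(wave_type = wt, matched = sum(used_g),
                                  missed = sum(!used_g),
                                  spurious = sum(!used_p)),
         errors = if (length(pairs)) dplyr::bind_rows(pairs))
  }
  parts <- lapply(c("P", "QRS", "T"), per_type)
  errors <- dplyr::bind_rows(lapply(parts, `[[`, "errors"))
  if (nrow(errors)) {
    errors$onset_error_ms <- errors$onset_error / fs * 1000
    errors$offset_error_ms <- errors$offset_error / fs * 1000
  }
  list(summary = dplyr::bind_rows(lapply(parts, `[[`, "summary")),
       errors = errors)
}
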