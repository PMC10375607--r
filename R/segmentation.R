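#' Fixed beat-window length in samples
#' @return 512L
#' @export
beat_window_length <- function() 512L

#' Locate beat boundaries on one lead
#'
#' A beat spans one P-wave onset to the next P-wave onset. A span is emitted
#' only when it contains a complete P triplet (the one opening it) and at
#' least one complete QRS triplet; the trailing partial beat after the last
#' P onset is never emitted.
#'
#' @param triplets One lead's triplets (from [pair_wave_triplets()]).
#' @return Tibble with columns `start`, `end` (0-based, end exclusive);
#'   attribute `excluded` = number of candidate spans dropped by the
#'   completeness rule.
#' @export
locate_beat_boundaries <- function(triplets) {
  triplets <- dplyr::arrange(triplets, .data$onset)
  p_on <- triplets$onset[triplets$wave_type == "P"]
  out <- tibble::tibble(start = integer(), end = integer())
  excluded <- 0L
  if (length(p_on) >= 2L) {
    for (k in seq_len(length(p_on) - 1L)) {
      s <- p_on[k]; e <- p_on[k + 1L]
      has_qrs <- any(triplets$wave_type == "QRS" &
                       triplets$onset >= s & triplets$offset < e)
      if (has_qrs) {
        out <- dplyr::bind_rows(out, tibble::tibble(start = s, end = e))
      } else {
        excluded <- excluded + 1L
      }
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Extract fixed-length beat windows from one lead
#'
#' Cuts the lead's signal at the boundaries from [locate_beat_boundaries()],
#' zero-pads each window to 512 samples (or clips it at 512 when the span is
#' longer), and attaches the per-sample label stream re-based to window
#' coordinates. Labels and signal in the padded tail are 0, and
#' `valid_length` records how many samples are real.
#'
#' @param record An [ecg_record()].
#' @param triplets Triplet table for `lead` (columns `wave_type`, `onset`,
#'   `peak`, `offset`).
#' @param lead Lead name.
#' @return Tibble with columns `record_id`, `lead`, `beat_index`,
#'   `start_sample`, `valid_length` and list-columns `signal`, `labels`
#'   (each element length 512); attribute `clipped` = number of spans longer
#'   than 512 that were clipped.
#' @export
extract_beat_windows <- function(record, triplets, lead) {
  lead <- match.arg(lead, ecg_leads())
  width <- beat_window_length()
  bounds <- locate_beat_boundaries(triplets)
  if (nrow(bounds) && any(bounds$end <= bounds$start)) {
    stop("internal consistency error: beat end <= start", call. = FALSE)
  }
  full_labels <- build_label_stream(triplets, record$n_samples)
  sig <- record$signals[, lead]
  clipped <- 0L
  rows <- purrr::map(seq_len(nrow(bounds)), function(k) {
    s <- bounds$start[k]; e <- bounds$end[k]
    span <- e - s
    if (span > width) clipped <<- clipped + 1L
    vl <- min(span, width)
    w_sig <- numeric(width)
    w_lab <- integer(width)
    w_sig[seq_len(vl)] <- sig[(s + 1L):(s + vl)]
    w_lab[seq_len(vl)] <- full_labels[(s + 1L):(s + vl)]
    tibble::tibble(record_id = record$record_id, lead = lead,
                   beat_index = k, start_sample = s, valid_length = vl,
                   signal = list(w_sig), labels = list(w_lab))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(record_id = character(), lead = character(),
                   beat_index = integer(), start_sample = integer(),
                   valid_length = integer(), signal = list(), labels = list())
  attr(out, "clipped") <- clipped
  out
}

#' Segment every lead of a record
#'
#' @param record An [ecg_record()].
#' @param triplets Triplet table with a `lead` column
#'   (from [read_record_triplets()]).
#' @return Beat-window tibble over all leads (see [extract_beat_windows()]).
#' @export
segment_record <- function(record, triplets) {
  purrr::map_dfr(ecg_leads(), function(ld) {
    tr <- triplets[triplets$lead == ld, ]
    extract_beat_windows(record, tr, ld)
  })
}

#' Split specification
#'
#' Defines how beats are partitioned into training / validation / test sets.
#' `beat_based` shuffles beats within each lead and partitions by fractions;
#' `patient_based` partitions whole records by record-id range, with no
#' randomness, so no subject's beats can leak across sets.
#'
#' @param mode `"beat_based"` or `"patient_based"`.
#' @param fractions Length-3 numeric (train, validation, test) summing to 1.
#' @param patient_ranges List of 3 integer vectors of record ids
#'   (train, validation, test); defaults to records 1-180 / 181-190 /
#'   191-200.
#' @param seed Shuffle seed for `beat_based`.
#' @return A `split_spec` list.
#' @export
split_spec <- function(mode = c("patient_based", "beat_based"),
                       fractions = c(train = 0.80, validation = 0.12, test = 0.08),
                       patient_ranges = list(train = 1:180,
                                             validation = 181:190,
                                             test = 191:200),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "beat_based") {
    if (length(fractions) != 3L || any(fractions < 0) ||
        abs(sum(fractions) - 1) > 1e-8) {
      stop("fractions must be 3 non-negative numbers summing to 1",
           call. = FALSE)
    }
  } else {
    if (length(patient_ranges) != 3L ||
        length(Reduce(intersect, patient_ranges)) > 0L) {
      stop("patient_ranges must be 3 disjoint id vectors", call. = FALSE)
    }
    pair_overlap <- any(vapply(utils::combn(3L, 2L, simplify = FALSE),
                               function(ij) length(intersect(patient_ranges[[ij[1]]],
                                                             patient_ranges[[ij[2]]])) > 0L,
                               logical(1)))
    if (pair_overlap) stop("patient_ranges must be disjoint", call. = FALSE)
  }
  structure(list(mode = mode, fractions = fractions,
                 patient_ranges = patient_ranges, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition beats into train / validation / test collections
#'
#' @param beats Beat-window tibble (must carry `record_id` and `lead`).
#' @param spec A [split_spec()].
#' @return Named list `train`, `validation`, `test` of disjoint beat tibbles
#'   whose union is the input.
#' @export
make_split <- function(beats, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (spec$mode == "patient_based") {
    ids <- suppressWarnings(as.integer(beats$record_id))
    if (anyNA(ids)) {
      stop("patient_based split needs integer-valued record ids",
           call. = FALSE)
    }
    uncovered <- setdiff(unique(ids), unlist(spec$patient_ranges))
    if (length(uncovered)) {
      stop("record id(s) not covered by patient_ranges: ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    }
    list(train = beats[ids %in% spec$patient_ranges[[1L]], ],
         validation = beats[ids %in% spec$patient_ranges[[2L]], ],
         test = beats[ids %in% spec$patient_ranges[[3L]], ])
  } else {
    f <- spec$fractions
    withr_seed <- spec$seed
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(withr_seed)
    parts <- list(train = list(), validation = list(), test = list())
    for (ld in unique(as.character(beats$lead))) {
      b <- beats[beats$lead == ld, ]
      n <- nrow(b)
      ord <- sample.int(n)
      n_tr <- floor(f[[1L]] * n)
      n_tv <- floor((f[[1L]] + f[[2L]]) * n)
      parts$train[[ld]] <- b[ord[seq_len(n_tr)], ]
      parts$validation[[ld]] <- b[ord[seq.int(n_tr + 1L, length.out = n_tv - n_tr)], ]
      parts$test[[ld]] <- b[ord[seq.int(n_tv + 1L, length.out = n - n_tv)], ]
    }
    lapply(parts, dplyr::bind_rows)
  }
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
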