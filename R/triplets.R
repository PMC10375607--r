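#' Wave classes
#'
#' Integer label codes for the four sample classes: 0 isoelectric, 1 P wave,
#' 2 QRS complex, 3 T wave.
#'
#' @return Named integer vector.
#' @export
wave_classes <- function() c(iso = 0L, P = 1L, QRS = 2L, T = 3L)

# LUDB peak-symbol convention; other WFDB dialects can pass their own map
.default_peak_map <- c(p = "P", N = "QRS", t = "T")

#' Pair raw annotations into wave triplets
#'
#' Scans an ordered (symbol, sample) annotation stream and pairs each maximal
#' `'('`, peak-symbol, `')'` run into one wave triplet, typed by the peak
#' symbol (`p` = P, `N` = QRS, `t` = T under the LUDB convention). Runs
#' missing their onset `'('` or offset `')'` — including two consecutive peak
#' symbols with no boundary between them — are dropped and counted in the
#' exclusion tally returned as the `excluded` attribute.
#'
#' @param annotations Tibble with columns `symbol`, `sample`
#'   (from [read_lead_annotations()]), sorted by `sample`.
#' @param peak_map Named character vector mapping peak symbols to wave types.
#' @return Tibble with columns `wave_type` (factor P/QRS/T), `onset`, `peak`,
#'   `offset` (0-based sample indices, onset <= peak <= offset), with
#'   attribute `excluded` = number of dropped incomplete runs.
#' @export
pair_wave_triplets <- function(annotations, peak_map = .default_peak_map) {
  stopifnot(all(c("symbol", "sample") %in% names(annotations)))
  if (is.unsorted(annotations$sample)) {
    annotations <- annotations[order(annotations$sample), ]
  }
  n <- nrow(annotations)
  wt <- character(0); on <- integer(0); pk <- integer(0); off <- integer(0)
  excluded <- 0L
  open <- NA_integer_
  peak_sym <- NA_character_; peak_at <- NA_integer_
  flush_incomplete <- function() {
    # one incomplete run = whatever symbols are pending
    if (!is.na(open) || !is.na(peak_sym)) excluded <<- excluded + 1L
    open <<- NA_integer_; peak_sym <<- NA_character_; peak_at <<- NA_integer_
  }
  for (k in seq_len(n)) {
    s <- annotations$symbol[k]
    at <- annotations$sample[k]
    if (s == "(") {
      flush_incomplete()
      open <- at
    } else if (s %in% names(peak_map)) {
      if (!is.na(peak_sym)) {
        # two consecutive peaks with no boundary: both runs incomplete
        excluded <- excluded + 2L
        open <- NA_integer_; peak_sym <- NA_character_; peak_at <- NA_integer_
      } else {
        peak_sym <- s; peak_at <- at
      }
    } else if (s == ")") {
      if (!is.na(open) && !is.na(peak_sym)) {
        wt <- c(wt, peak_map[[peak_sym]])
        on <- c(on, open); pk <- c(pk, peak_at); off <- c(off, at)
        open <- NA_integer_; peak_sym <- NA_character_; peak_at <- NA_integer_
      } else {
        flush_incomplete()  # ')' closing a run that lacked '(' or a peak
      }
    } else {
      stop("unknown annotation symbol '", s, "' at sample ", at, call. = FALSE)
    }
  }
  flush_incomplete()
  out <- tibble::tibble(
    wave_type = factor(wt, levels = c("P", "QRS", "T")),
    onset = on, peak = pk, offset = off
  )
  attr(out, "excluded") <- excluded
  out
}

#' Build a per-sample label stream from wave triplets
#'
#' Every sample inside a triplet's closed interval `[onset, offset]` receives
#' the wave's class code; all other samples are 0 (isoelectric). Where
#' intervals overlap the precedence is QRS > T > P.
#'
#' @param triplets Tibble with `wave_type`, `onset`, `offset` (0-based).
#' @param n Stream length in samples.
#' @return Integer vector of length `n` with values in `0:3`
#'   (see [wave_classes()]).
#' @export
build_label_stream <- function(triplets, n) {
  labels <- integer(n)
  if (nrow(triplets) == 0L) return(labels)
  bad <- triplets$onset < 0L | triplets$offset >= n |
    triplets$onset > triplets$offset
  if (any(bad)) {
    b <- triplets[which(bad)[1L], ]
    stop("triplet out of range for n = ", n, ": ", b$wave_type,
         " [", b$onset, ", ", b$offset, "]", call. = FALSE)
  }
  codes <- wave_classes()
  # apply in increasing precedence so later writes win: P, then T, then QRS
  for (w in c("P", "T", "QRS")) {
    rows <- triplets[triplets$wave_type == w, ]
    for (k in seq_len(nrow(rows))) {
      labels[(rows$onset[k] + 1L):(rows$offset[k] + 1L)] <- codes[[w]]
    }
  }
  labels
}

#' Write wave triplets to a tab-separated file
#'
#' @param triplets Tibble with columns `record_id`, `lead`, `wave_type`,
#'   `onset`, `peak`, `offset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read all leads' triplets for one record
#'
#' Convenience wrapper: parses every lead's annotation file of a record and
#' binds the paired triplets into one table.
#'
#' @inheritParams read_lead_annotations
#' @param leads Leads to read (default all 12).
#' @return Tibble with columns `lead`, `wave_type`, `onset`, `peak`,
#'   `offset`; attribute `excluded` = total exclusion tally.
#' @export
read_record_triplets <- function(path, record_id, leads = ecg_leads()) {
  excluded <- 0L
  out <- purrr::map_dfr(leads, function(ld) {
    ann <- read_lead_annotations(path, record_id, ld)
    tr <- pair_wave_triplets(ann)
    excluded <<- excluded + attr(tr, "excluded")
    tr$lead <- rep(ld, nrow(tr))
    tr
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(lead = character(), wave_type = factor(levels = c("P", "QRS", "T")),
                          onset = integer(), peak = integer(), offset = integer())
  }
  out <- dplyr::relocate(out, "lead")
  out$lead <- factor(out$lead, levels = ecg_leads())
  attr(out, "excluded") <- excluded
  out
}
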