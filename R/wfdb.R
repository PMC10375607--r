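#' Canonical 12-lead order
#'
#' The standard lead order used throughout the package: the six limb leads
#' (I, II, III, aVR, aVL, aVF) followed by the six chest leads (V1-V6).
#'
#' @return Character vector of the 12 lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# annotation file extensions used by the LUDB per-lead dialect
.lead_ext <- function(lead) tolower(lead)

#' Construct a 12-lead ECG record
#'
#' @param record_id Record identifier string.
#' @param fs Sampling rate in Hz.
#' @param signals Numeric matrix, samples x 12 leads (mV), columns in
#'   [ecg_leads()] order.
#' @return An `ecg_record` object.
#' @export
ecg_record <- function(record_id, fs, signals) {
  stopifnot(is.matrix(signals), is.numeric(signals))
  if (ncol(signals) != 12L) {
    stop("signals must have 12 columns (one per lead)", call. = FALSE)
  }
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  colnames(signals) <- ecg_leads()
  structure(list(record_id = as.character(record_id), fs = fs,
                 signals = signals, n_samples = nrow(signals)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record> ", x$record_id, ": ", x$n_samples, " samples x 12 leads @ ",
      x$fs, " Hz (", round(x$n_samples / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.ecg_record <- function(x, ...) {
  tibble::tibble(
    record_id = x$record_id,
    sample = rep(seq_len(x$n_samples) - 1L, times = 12L),
    time_s = rep((seq_len(x$n_samples) - 1L) / x$fs, times = 12L),
    lead = factor(rep(ecg_leads(), each = x$n_samples), levels = ecg_leads()),
    mv = as.vector(x$signals)
  )
}

# ---- WFDB header + signal files (format 16) ---------------------------------

#' Write an ECG record as a WFDB record
#'
#' Writes `<record_id>.hea` and `<record_id>.dat` (format 16, gain 1000
#' ADC units/mV) into `dir`.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if needed).
#' @param gain ADC gain, units per mV.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, gain = 1000) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory ", dir, call. = FALSE)
  }
  dig <- round(record$signals * gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  hea <- file.path(dir, paste0(record$record_id, ".hea"))
  dat <- paste0(record$record_id, ".dat")
  lines <- c(
    paste(record$record_id, 12L, record$fs, record$n_samples),
    vapply(seq_len(12L), function(i) {
      paste(dat, 16L, paste0(gain, "(0)/mV"), 16L, 0L, dig[1L, i], 0L, 0L,
            ecg_leads()[i])
    }, character(1))
  )
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  invisible(hea)
}

.parse_gain <- function(tok) {
  # "1000(0)/mV" | "1000/mV" | "1000" ; WFDB default gain is 200
  core <- sub("/.*$", "", tok)
  baseline <- 0
  if (grepl("\\(", core)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", core))
    core <- sub("\\(.*$", "", core)
  }
  g <- suppressWarnings(as.numeric(core))
  if (is.na(g) || g == 0) g <- 200
  list(gain = g, baseline = baseline)
}

#' Read a WFDB record
#'
#' Reads `<record_id>.hea` and its format-16 signal file, converts ADC units
#' to mV using the per-signal gain and baseline, and returns the 12 leads in
#' canonical order regardless of their order on disk.
#'
#' @param path Directory holding the record files.
#' @param record_id Record name (header is `<record_id>.hea`).
#' @return An [ecg_record()].
#' @export
read_record <- function(path, record_id) {
  hea <- file.path(path, paste0(record_id, ".hea"))
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_tok[2L])
  fs <- as.numeric(sub("/.*$", "", head_tok[3L]))
  if (is.na(fs)) fs <- 250
  nsamp <- as.integer(head_tok[4L])
  sig_lines <- lines[seq.int(2L, length.out = nsig)]
  toks <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  desc <- vapply(toks, function(t) paste(t[seq.int(9L, length(t))], collapse = " "),
                 character(1))
  fmt <- vapply(toks, function(t) sub("x.*$", "", t[2L]), character(1))
  if (any(fmt != "16")) {
    stop("unsupported WFDB signal format(s): ",
         paste(unique(fmt[fmt != "16"]), collapse = ", "), call. = FALSE)
  }
  gains <- lapply(toks, function(t) .parse_gain(t[3L]))
  datf <- unique(vapply(toks, `[`, character(1), 1L))
  if (length(datf) != 1L) {
    stop("multi-file records are not supported", call. = FALSE)
  }
  datp <- file.path(path, datf)
  if (!file.exists(datp)) stop("signal file not found: ", datp, call. = FALSE)
  raw <- readBin(datp, what = "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp) {
    stop("signal file shorter than header promises: ", datp, call. = FALSE)
  }
  dig <- matrix(raw, ncol = nsig, byrow = TRUE)
  phys <- sweep(dig, 2L, vapply(gains, `[[`, numeric(1), "baseline"))
  phys <- sweep(phys, 2L, vapply(gains, `[[`, numeric(1), "gain"), "/")
  idx <- match(tolower(ecg_leads()), tolower(desc))
  if (anyNA(idx)) {
    stop("record ", record_id, " is missing lead(s): ",
         paste(ecg_leads()[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ecg_record(record_id, fs, phys[, idx, drop = FALSE])
}

# ---- MIT-format annotation files --------------------------------------------

# annotation codes used by the LUDB wave-boundary dialect
.ann_code_symbol <- c(`1` = "N", `24` = "p", `27` = "t", `39` = "(", `40` = ")")
.ann_symbol_code <- stats::setNames(as.integer(names(.ann_code_symbol)),
                                    .ann_code_symbol)

#' Read one lead's wave-boundary annotations
#'
#' Reads a WFDB (MIT-format) annotation file named
#' `<record_id>.<lead extension>` (e.g. `1.avr` for lead aVR) and returns the
#' annotation symbols with their sample indices. Only the wave-boundary
#' dialect is accepted: `(` and `)` for onsets/offsets and `p`, `N`, `t` for
#' P, QRS and T peaks.
#'
#' @param path Directory holding the annotation file.
#' @param record_id Record name.
#' @param lead Lead name (one of [ecg_leads()]).
#' @return Tibble with columns `symbol` and `sample` (0-based, non-decreasing).
#' @export
read_lead_annotations <- function(path, record_id, lead) {
  lead <- match.arg(lead, ecg_leads())
  fp <- file.path(path, paste0(record_id, ".", .lead_ext(lead)))
  if (!file.exists(fp)) stop("annotation file not found: ", fp, call. = FALSE)
  bytes <- readBin(fp, "integer", n = file.size(fp), size = 1L, signed = FALSE)
  syms <- character(0)
  samp <- integer(0)
  t <- 0
  i <- 1L
  while (i + 1L <= length(bytes)) {
    word <- bytes[i] + 256L * bytes[i + 1L]
    code <- word %/% 1024L
    delta <- word %% 1024L
    i <- i + 2L
    if (code == 0L && delta == 0L) break            # EOF
    if (code == 59L) {                              # SKIP: 4-byte interval
      w1 <- bytes[i] + 256L * bytes[i + 1L]
      w2 <- bytes[i + 2L] + 256L * bytes[i + 3L]
      t <- t + w1 * 65536 + w2
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L)) {        # NUM / SUB / CHN: no time
    } else if (code == 63L) {                       # AUX: skip payload
      i <- i + delta + delta %% 2L
    } else {
      t <- t + delta
      sym <- .ann_code_symbol[as.character(code)]
      if (is.na(sym)) {
        stop("unknown annotation code ", code, " at sample ", t, " in ", fp,
             call. = FALSE)
      }
      syms <- c(syms, unname(sym))
      samp <- c(samp, as.integer(t))
    }
  }
  tibble::tibble(symbol = syms, sample = samp)
}

#' Write one lead's annotations in MIT format
#'
#' Inverse of [read_lead_annotations()]; writes the wave-boundary symbol
#' dialect with delta-encoded sample times (long gaps via SKIP words).
#'
#' @param annotations Tibble with columns `symbol` and `sample`.
#' @param path Output directory.
#' @param record_id Record name.
#' @param lead Lead name.
#' @return The file path, invisibly.
#' @export
write_lead_annotations <- function(annotations, path, record_id, lead) {
  lead <- match.arg(lead, ecg_leads())
  stopifnot(all(annotations$symbol %in% names(.ann_symbol_code)))
  stopifnot(!is.unsorted(annotations$sample))
  fp <- file.path(path, paste0(record_id, ".", .lead_ext(lead)))
  words <- integer(0)
  t <- 0
  for (k in seq_len(nrow(annotations))) {
    delta <- annotations$sample[k] - t
    code <- .ann_symbol_code[[annotations$symbol[k]]]
    if (delta > 1023L) {
      words <- c(words, 59L * 1024L,
                 delta %/% 65536L, delta %% 65536L)
      delta <- 0L
    }
    words <- c(words, code * 1024L + delta)
    t <- annotations$sample[k]
  }
  words <- c(words, 0L)  # EOF
  bytes <- as.integer(rbind(words %% 256L, words %/% 256L))
  con <- file(fp, "wb")
  on.exit(close(con))
  writeBin(bytes, con, size = 1L)
  invisible(fp)
}
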