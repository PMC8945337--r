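#' Write a recording to disk
#'
#' Two formats are supported. `csv` is the lossless interchange dialect:
#' UTF-8, comment lines `# key: value` carrying `fs_hz`, `modality`,
#' `subject_id`, `condition` and `units`, a `time_s,value` header, then one
#' row per sample at full decimal precision (17 significant digits, so the
#' round trip is bit exact). `edf` is the archival option: one signal per
#' file, 16-bit European Data Format; amplitudes are quantized onto the
#' record's physical range, so the round trip is lossy by at most one
#' quantization step of `(max - min) / 65535`.
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(record, path, format = c("csv", "edf")) {
  stopifnot(inherits(record, "signal_record"))
  format <- match.arg(format)
  if (length(record$samples) == 0)
    stop("write_recording: record has no samples", call. = FALSE)
  if (format == "csv") write_recording_csv(record, path)
  else write_recording_edf(record, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. For CSV input, header metadata is
#' required; if a `time_s` column is present it must be consistent with
#' the declared sampling rate to within half a sample period, and any
#' missing or non-finite sample value is a format error (never silently
#' imputed).
#'
#' @param path Input file path.
#' @param format `"csv"` or `"edf"`. Defaults to the file extension.
#' @return A validated [signal_record()].
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("read_recording: file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "edf"))
      stop("read_recording: cannot infer format from extension '",
           format, "'; pass format explicitly", call. = FALSE)
  }
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
}

write_recording_csv <- function(record, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(fs_hz = format(record$fs, digits = 17),
            modality = record$modality,
            subject_id = record$subject_id,
            condition = record$condition,
            units = record$units)
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines("time_s,value", con)
  t <- (seq_along(record$samples) - 1) / record$fs
  writeLines(paste(sprintf("%.17g", t), sprintf("%.17g", record$samples),
                   sep = ","), con)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  for (key in c("fs_hz", "modality", "subject_id", "condition", "units"))
    if (is.null(meta[[key]]))
      stop("read_recording: missing header metadata field '", key, "'",
           call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (!is.finite(fs) || fs <= 0)
    stop("read_recording: invalid fs_hz header value '", meta$fs_hz, "'",
         call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2)
    stop("read_recording: no data rows", call. = FALSE)
  dat <- utils::read.csv(text = body, header = TRUE)
  if (!"value" %in% names(dat))
    stop("read_recording: missing 'value' column", call. = FALSE)
  if (any(!is.finite(dat$value)))
    stop("read_recording: non-finite sample values in 'value' column",
         call. = FALSE)
  if ("time_s" %in% names(dat)) {
    if (any(!is.finite(dat$time_s)) || is.unsorted(dat$time_s,
                                                   strictly = TRUE))
      stop("read_recording: time_s column must be finite and strictly ",
           "increasing", call. = FALSE)
    expected <- (seq_len(nrow(dat)) - 1) / fs
    if (max(abs(dat$time_s - expected)) > 0.5 / fs)
      stop("read_recording: time_s column inconsistent with fs_hz = ", fs,
           " (deviates by more than half a sample period)", call. = FALSE)
  }
  signal_record(dat$value, fs, meta$modality, meta$subject_id,
                meta$condition, units = meta$units)
}

# --- Minimal single-signal EDF support -------------------------------------
# European Data Format: 256-byte fixed header, 256 bytes of signal header,
# then 16-bit little-endian samples. The whole record is written as a
# single EDF data record whose duration is the record length in seconds,
# which keeps the sample count exact on the round trip. No installed R
# package reads EDF, so this small reader/writer is implemented here.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(record, path) {
  x <- record$samples
  n <- length(x)
  fs <- record$fs
  dur <- n / fs
  pmin_ <- min(x)
  pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1  # constant signal: unit range
  dmin <- -32768
  dmax <- 32767
  dig <- round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste(record$subject_id, record$condition), 80),
    edf_pad(paste("modality", record$modality), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(512, 8),                      # header bytes: 256 + 1 * 256
    edf_pad("", 44),
    edf_pad(1, 8),                        # number of data records
    edf_pad(format(dur, digits = 8), 8),  # record duration, s
    edf_pad(1, 4))                        # number of signals
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    edf_pad(record$modality, 16),
    edf_pad("synthetic", 80),
    edf_pad(record$units, 8),
    edf_pad(format(pmin_, digits = 8), 8),
    edf_pad(format(pmax_, digits = 8), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8),
    edf_pad("", 80),
    edf_pad(n, 8),
    edf_pad("", 32))
  writeChar(sig, con, eos = NULL)
  writeBin(as.integer(dig), con, size = 2, endian = "little")
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  patient <- strsplit(fld(hdr, 9, 80), "\\s+")[[1]]
  subject_id <- if (length(patient) >= 1) patient[1] else "S01"
  condition <- if (length(patient) >= 2 &&
                   patient[2] %in% c("caffeine", "placebo"))
    patient[2] else "placebo"
  n_rec <- as.integer(fld(hdr, 237, 8))
  dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (!identical(ns, 1L))
    stop("read_recording: only single-signal EDF files are supported",
         call. = FALSE)
  sig <- readChar(con, 256, useBytes = TRUE)
  label <- fld(sig, 1, 16)
  units <- fld(sig, 97, 8)
  pmin_ <- as.numeric(fld(sig, 105, 8))
  pmax_ <- as.numeric(fld(sig, 113, 8))
  dmin <- as.numeric(fld(sig, 121, 8))
  dmax <- as.numeric(fld(sig, 129, 8))
  nsamp <- as.integer(fld(sig, 217, 8))
  dig <- readBin(con, integer(), n = nsamp * n_rec, size = 2,
                 signed = TRUE, endian = "little")
  x <- (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  fs <- nsamp / dur
  modality <- if (label %in% c("ECG", "EDA", "RF")) label else "RF"
  signal_record(x, fs, modality, subject_id, condition, units = units)
}
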