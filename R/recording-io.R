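#' @include accessors.R regions.R
NULL

#' Read a multichannel EEG recording
#'
#' Reads either an EDF/EDF+ file (16-bit, one or more data records) or the
#' delimited matrix format written by [writeRecording()]: a TSV with one row
#' per channel (first column the channel label) accompanied by a JSON
#' sidecar `<path>.json` holding `rate` and `labels`, or alternatively a
#' first header line of the form `# rate=250; labels=C3,C4`.
#'
#' Channel labels are normalized to canonical 10-20 capitalization
#' (T7/T8/P7/P8 are accepted as synonyms of T3/T4/T5/T6); labels that are
#' not 10-20 positions are preserved and flagged in `recordingMeta(x)$unknown_labels`.
#'
#' @param path file path.
#' @param format "auto" (by extension), "edf", or "matrix".
#' @return An [EEGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") .readEDF(path) else .readMatrixRecording(path)
}

#' Write a recording to disk
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @param format "matrix" (TSV plus JSON sidecar) or "edf" (16-bit EDF with
#'   one-second data records; the duration is truncated to whole seconds).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (format == "matrix") .writeMatrixRecording(rec, path) else .writeEDF(rec, path)
  invisible(path)
}

.readMatrixRecording <- function(path) {
  sidecar <- paste0(path, ".json")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("input error: empty file: ", path)
  rate <- NULL; labels <- NULL; skip <- 0L
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rate <- side$rate; labels <- side$labels
  }
  if (startsWith(first, "#")) {
    skip <- 1L
    if (is.null(rate)) {
      rate <- suppressWarnings(as.numeric(sub(".*rate\\s*=\\s*([0-9.eE+-]+).*", "\\1", first)))
      if (grepl("labels\\s*=", first))
        labels <- trimws(strsplit(sub(".*labels\\s*=\\s*([^;]+).*", "\\1", first), ",")[[1]])
    }
  }
  if (is.null(rate) || !is.finite(rate))
    stop("format error: sampling rate not found (need a JSON sidecar or '# rate=...' header)")
  dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = skip,
                          data.table = FALSE)
  if (is.character(dt[[1]])) {
    rowLabels <- dt[[1]]
    mat <- as.matrix(dt[, -1, drop = FALSE])
    if (is.null(labels)) labels <- rowLabels
  } else {
    mat <- as.matrix(dt)
    if (is.null(labels)) stop("format error: channel labels not found")
  }
  if (anyDuplicated(labels))
    stop("format error: duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  nl <- normalizeLabels(labels)
  EEGRecording(unname(mat), rate = rate, labels = nl$labels,
               meta = list(source = path, format = "matrix",
                           unknown_labels = nl$unknown))
}

.writeMatrixRecording <- function(rec, path) {
  df <- data.frame(label = rec@labels, rec@samples, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  jsonlite::write_json(list(rate = rec@rate, labels = rec@labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

# --- minimal EDF (16-bit) support ------------------------------------------

.padField <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf("%-*s", width, x)
}

.writeEDF <- function(rec, path) {
  fs <- rec@rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writing requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec@samples)
  nrec <- ncol(rec@samples) %/% fs
  if (nrec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (nrec * fs < ncol(rec@samples))
    warning("EDF output truncated to ", nrec, " whole seconds")
  x <- rec@samples[, seq_len(nrec * fs), drop = FALSE]
  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * 1.0001, 1)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.padField("0", 8), .padField("synthetic subject", 80),
                .padField("eegconn export", 80), "01.01.00", "00.00.00",
                .padField(256L * (1L + ns), 8), .padField("", 44),
                .padField(nrec, 8), .padField(1, 8), .padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(rec@labels, .padField, "", width = 16), collapse = ""),
    paste(rep(.padField("", 80), ns), collapse = ""),
    paste(rep(.padField("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax_, function(v) .padField(sprintf("%.6g", v), 8), ""), collapse = ""),
    paste(vapply(pmax_, function(v) .padField(sprintf("%.6g", v), 8), ""), collapse = ""),
    paste(rep(.padField(dmin, 8), ns), collapse = ""),
    paste(rep(.padField(dmax, 8), ns), collapse = ""),
    paste(rep(.padField("", 80), ns), collapse = ""),
    paste(rep(.padField(fs, 8), ns), collapse = ""),
    paste(rep(.padField("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, cols] + pmax_[ch]) * scale[ch]) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) suppressWarnings(as.numeric(trimws(rd(n))))
  rd(8 + 80 + 80 + 8 + 8)
  hdrBytes <- num(8)
  rd(44)
  nrec <- num(8)
  recDur <- num(8)
  ns <- as.integer(num(4))
  if (!is.finite(ns) || ns < 1) stop("format error: bad EDF signal count")
  fld <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (!is.finite(recDur) || recDur <= 0)
    stop("format error: missing EDF record duration")
  if (length(unique(spr)) != 1L)
    stop("format error: signals with differing sampling rates are not supported")
  if (anyDuplicated(labels))
    stop("format error: duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  seek(con, hdrBytes)
  nrec <- as.integer(nrec)
  out <- matrix(0, ns, nrec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        pmin_[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  nl <- normalizeLabels(labels)
  EEGRecording(out, rate = spr[1] / recDur, labels = nl$labels,
               meta = list(source = path, format = "edf",
                           unknown_labels = nl$unknown))
}
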