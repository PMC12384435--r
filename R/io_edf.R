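# Minimal EDF (European Data Format) support: 16-bit signals, one data
# record per second. Covers plain EDF only (no EDF+ annotation streams), so
# state annotations travel via the delimited/container formats instead.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over each channel's physical range and
#' stored in one-second data records; the recording is truncated to a whole
#' number of seconds. Annotations are not representable in plain EDF and are
#' dropped (use the delimited or container formats to keep them).
#'
#' @param rec an [eeg_recording()]; `rec$fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  X <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(X, 1L, min)
  pmax <- apply(X, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$subject_id, 80),
    .edf_pad(rec$session_id, 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256L * (ns + 1L), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin, format = "g", digits = 6), 8)
  field(formatC(pmax, format = "g", digits = 6), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round((X[, idx, drop = FALSE] - pmin) * scale + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    # per-signal sequential storage within the record
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.edf_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (any(!is.finite(v))) stop("EDF header field '", what, "' is not numeric")
  v
}

#' Read an EDF file into a recording
#'
#' @param path an EDF file as written by [write_edf()] or any plain 16-bit
#'   EDF with a constant per-signal sampling rate.
#' @return An [eeg_recording()] (no annotations; plain EDF carries none).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                       # version
  subject <- trimws(rd(80))
  session <- trimws(rd(80))
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(.edf_num(rd(8), "number of data records"))
  rec_dur <- .edf_num(rd(8), "data record duration")
  if (rec_dur <= 0) stop("EDF data record duration must be positive")
  ns <- as.integer(.edf_num(rd(4), "number of signals"))
  if (ns < 1L) stop("EDF file declares 0 signals")
  rdf <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- rdf(16)
  rdf(80); rdf(8)
  pmin <- .edf_num(rdf(8), "physical minimum")
  pmax <- .edf_num(rdf(8), "physical maximum")
  dmin <- .edf_num(rdf(8), "digital minimum")
  dmax <- .edf_num(rdf(8), "digital maximum")
  rdf(80)
  spr <- as.integer(.edf_num(rdf(8), "samples per record"))
  rdf(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  if (!is.finite(fs) || fs <= 0) stop("EDF sampling rate missing or invalid")

  X <- matrix(0, ns, n_rec * spr[1L])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1L]) stop("EDF file truncated at record ", r)
    block <- matrix(raw, nrow = spr[1L], ncol = ns)  # signal-major in record
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    X[, idx] <- t((block - rep(dmin, each = spr[1L])) *
                    rep(scale, each = spr[1L]) + rep(pmin, each = spr[1L]))
  }
  eeg_recording(X, fs, labels,
                subject_id = if (nzchar(subject)) subject else "S1",
                session_id = if (nzchar(session)) session else "R1")
}
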