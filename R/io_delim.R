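# Delimited-text and JSON-container recording formats. Both carry sampling
# rate, channel labels and annotations in-file, so round trips are complete;
# the delimited format stores one column per channel with metadata in
# leading '#' comment lines:
#
#   # fs: 128
#   # subject: S1
#   # session: R1
#   # units: uV
#   # annotation: 0 0 600
#   F3,Fz,F4,...
#   1.23,0.45,...
#
# Values are assumed microvolts unless '# units: V' is present (then
# converted). A delimited file without a '# fs:' line is rejected rather
# than guessed.

#' Write a recording as delimited text
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fs: ", format(rec$fs, digits = 15)),
    paste0("# subject: ", rec$subject_id),
    paste0("# session: ", rec$session_id),
    "# units: uV"
  ), con)
  if (nrow(rec$annotations))
    writeLines(sprintf("# annotation: %d %.9g %.9g", rec$annotations$label,
                       rec$annotations$start_s, rec$annotations$end_s), con)
  writeLines(paste(rec$channel_labels, collapse = sep), con)
  utils::write.table(t(rec$data), con, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.parse_delim_meta <- function(lines) {
  meta <- list(fs = NULL, subject = "S1", session = "R1", units = "uV",
               ann = list())
  for (ln in lines) {
    body <- trimws(sub("^#", "", ln))
    key <- tolower(trimws(sub(":.*$", "", body)))
    val <- trimws(sub("^[^:]*:", "", body))
    if (key == "fs") {
      fs <- suppressWarnings(as.numeric(val))
      if (!is.finite(fs)) stop("invalid '# fs:' value: ", val)
      meta$fs <- fs
    } else if (key == "subject") meta$subject <- val
    else if (key == "session") meta$session <- val
    else if (key == "units") meta$units <- val
    else if (key == "annotation") {
      parts <- suppressWarnings(as.numeric(strsplit(val, "[[:space:]]+")[[1]]))
      if (length(parts) != 3L || any(!is.finite(parts)))
        stop("invalid '# annotation:' line: ", ln)
      meta$ann[[length(meta$ann) + 1L]] <- parts
    }
  }
  meta
}

#' Read a delimited-text recording
#'
#' @param path a file written by [write_delimited()] (or any header-row
#'   delimited file with a `# fs:` comment line).
#' @param sep field separator; auto-detected between comma and tab when NULL.
#' @return An [eeg_recording()].
#' @export
read_delimited <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- .parse_delim_meta(lines[is_meta])
  if (is.null(meta$fs))
    stop("delimited recording is missing the sampling rate ('# fs:' line); ",
         "it is never guessed")
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop("delimited recording has no header row")
  if (is.null(sep)) sep <- if (grepl("\t", body[1L])) "\t" else ","
  labels <- trimws(strsplit(body[1L], sep, fixed = TRUE)[[1]])
  if (length(labels) == 0L || !any(nzchar(labels)))
    stop("delimited recording declares 0 channels")
  if (length(body) < 2L) stop("delimited recording has no samples")
  vals <- utils::read.table(text = body[-1L], sep = sep, header = FALSE,
                            colClasses = "numeric")
  if (ncol(vals) != length(labels))
    stop("header declares ", length(labels), " channels but rows have ",
         ncol(vals), " fields")
  X <- t(as.matrix(vals))
  dimnames(X) <- NULL
  if (identical(tolower(meta$units), "v")) X <- X * 1e6
  ann <- NULL
  if (length(meta$ann)) {
    m <- do.call(rbind, meta$ann)
    ann <- data.frame(label = m[, 1], start_s = m[, 2], end_s = m[, 3])
  }
  eeg_recording(X, meta$fs, labels, meta$subject, meta$session, ann)
}

#' Write a recording as a JSON array container
#'
#' The container is a single JSON object with keys `data` (channels x
#' samples), `fs`, `labels`, `subject`, `session` and `annotations`
#' (records of `label`, `start_s`, `end_s`). Values are microvolts.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param digits significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_container <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  obj <- list(
    data = rec$data, fs = rec$fs, labels = rec$channel_labels,
    subject = rec$subject_id, session = rec$session_id,
    annotations = rec$annotations
  )
  jsonlite::write_json(obj, path, digits = digits, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a JSON array-container recording
#' @param path a file written by [write_container()].
#' @return An [eeg_recording()].
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$fs)) stop("container is missing 'fs'; it is never guessed")
  if (is.null(obj$data)) stop("container is missing 'data'")
  X <- as.matrix(obj$data)
  dimnames(X) <- NULL
  if (nrow(X) == 0L) stop("container declares 0 channels")
  ann <- obj$annotations
  if (is.null(ann) || NROW(ann) == 0L) ann <- NULL
  eeg_recording(X, obj$fs, obj$labels,
                subject_id = obj$subject %||% "S1",
                session_id = obj$session %||% "R1",
                annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EEG recording from disk
#'
#' Dispatches on `format_hint`, or on the file extension when the hint is
#' `"auto"` (`.edf` -> EDF, `.json` -> container, anything else delimited).
#'
#' @param path input file.
#' @param format_hint `"auto"`, `"edf"`, `"delimited"` or `"container"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format_hint = c("auto", "edf", "delimited",
                                                 "container")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    ext <- tolower(tools::file_ext(path))
    format_hint <- switch(ext, edf = "edf", json = "container", "delimited")
  }
  switch(format_hint,
         edf = read_edf(path),
         delimited = read_delimited(path),
         container = read_container(path))
}

#' Write an EEG recording to disk
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param format `"auto"` (by extension), `"edf"`, `"delimited"` or
#'   `"container"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "delimited",
                                                  "container")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", json = "container", "delimited")
  }
  switch(format,
         edf = write_edf(rec, path),
         delimited = write_delimited(rec, path),
         container = write_container(rec, path))
}
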