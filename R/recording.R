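#' Construct an EEG recording container
#'
#' A recording is a channels-by-samples matrix (microvolts) plus sampling
#' rate, channel labels and non-overlapping, time-ordered state annotations.
#' State labels are the integers 0, 1, 2 (the mapping to dataset vocabularies
#' such as focused/unfocused/drowsy or neutral/relaxing/concentrating lives
#' in documentation, not in code).
#'
#' @param data numeric matrix, n_channels x n_samples, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param subject_id,session_id identifiers (coerced to character).
#' @param annotations data.frame with columns `label` (integer in 0..2),
#'   `start_s`, `end_s` (seconds, half-open intervals `[start_s, end_s)`),
#'   or NULL for an unannotated recording.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = "S1", session_id = "R1",
                          annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (channels x samples)")
  if (nrow(data) == 0L) stop("recording must have at least one channel")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") must equal the number of channels (", nrow(data), ")")
  dur <- ncol(data) / fs
  if (is.null(annotations)) {
    annotations <- data.frame(label = integer(0), start_s = numeric(0),
                              end_s = numeric(0))
  }
  annotations <- as.data.frame(annotations)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns label, start_s, end_s")
  annotations <- annotations[, need]
  annotations$label <- as.integer(annotations$label)
  if (nrow(annotations)) {
    if (any(!annotations$label %in% 0:2))
      stop("annotation labels must be 0, 1 or 2")
    if (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9))
      stop("annotation intervals must lie within [0, ", signif(dur, 6), "]")
    if (any(annotations$end_s <= annotations$start_s))
      stop("annotation intervals must have end_s > start_s")
    o <- order(annotations$start_s)
    annotations <- annotations[o, , drop = FALSE]
    if (nrow(annotations) > 1L &&
        any(annotations$start_s[-1L] < annotations$end_s[-nrow(annotations)] - 1e-9))
      stop("annotations must be non-overlapping")
    rownames(annotations) <- NULL
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", signif(ncol(x$data) / x$fs, 5), " s)\n",
      sep = "")
  cat("  subject ", x$subject_id, ", session ", x$session_id, "\n", sep = "")
  cat("  channels: ", paste(x$channel_labels, collapse = " "), "\n", sep = "")
  if (nrow(x$annotations)) {
    cat("  annotations:\n")
    for (i in seq_len(nrow(x$annotations)))
      cat(sprintf("    state %d: [%.1f, %.1f) s\n", x$annotations$label[i],
                  x$annotations$start_s[i], x$annotations$end_s[i]))
  } else cat("  (no annotations)\n")
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec an [eeg_recording()].
#' @return integer.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)
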