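#' Segmentation configuration
#'
#' Sliding-window segmentation parameters. The default window is 5 s with a
#' 6 s step, i.e. an overlap of -1 s (consecutive windows are separated by a
#' 1 s gap); `overlap_s` may be given instead of `step_s`, with
#' `step = window - overlap`. The first `drop_initial_s` seconds of every
#' annotated state block are discarded before cutting windows, removing
#' transient effects at state onset.
#'
#' @param window_s window length in seconds (> 0).
#' @param step_s step between window starts in seconds (> 0).
#' @param drop_initial_s seconds dropped at the start of each state block.
#' @param overlap_s optional overlap in seconds (e.g. -1, 1 or 3);
#'   overrides `step_s` when given.
#' @return List of class `"segmentation_config"`.
#' @export
segmentation_config <- function(window_s = 5, step_s = 6, drop_initial_s = 4,
                                overlap_s = NULL) {
  if (!is.null(overlap_s)) {
    if (overlap_s >= window_s) stop("overlap_s must be smaller than window_s")
    step_s <- window_s - overlap_s
  }
  if (window_s <= 0 || step_s <= 0 || drop_initial_s < 0)
    stop("window_s and step_s must be positive, drop_initial_s non-negative")
  structure(list(window_s = window_s, step_s = step_s,
                 drop_initial_s = drop_initial_s),
            class = "segmentation_config")
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order-per-pass Butterworth band-pass.
#' Zero phase keeps annotations aligned with the filtered signal.
#'
#' @param rec an [eeg_recording()].
#' @param band a band name (`"theta"`, `"alpha"`, `"beta"`) or a numeric
#'   `c(lo_hz, hi_hz)`.
#' @param order per-pass Butterworth order (default 4).
#' @return A filtered [eeg_recording()] (same geometry and annotations).
#' @export
bandpass_filter <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% names(bands)) stop("unknown band name: ", band)
    band <- bands[[band]]
  }
  if (length(band) != 2L || !all(is.finite(band)))
    stop("band must be c(lo_hz, hi_hz)")
  lo <- band[1L]; hi <- band[2L]
  if (lo <= 0 || lo >= hi) stop("band must satisfy 0 < lo_hz < hi_hz")
  if (hi >= rec$fs / 2)
    stop("band upper edge (", hi, " Hz) must be below Nyquist (",
         rec$fs / 2, " Hz)")
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  out
}

# ---- ICA ---------------------------------------------------------------

# Compact FastICA: whitening by eigendecomposition, tanh contrast,
# symmetric orthogonalization. Deterministic for a fixed seed.
.fastica <- function(X, n_comp, max_iter = 200L, tol = 1e-6, seed = 1L) {
  M <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-24)), n_comp) %*%
    t(eg$vectors[, keep, drop = FALSE])          # n_comp x M whitener
  Z <- K %*% Xc
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp * n_comp), n_comp)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  orth <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- orth(W)
  N <- ncol(Z)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / N - diag(rowMeans(Gp), n_comp) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z                                    # n_comp x N sources
  A <- pracma::pinv(W %*% K)                      # M x n_comp mixing
  list(S = S, A = A, mean = mu)
}

#' ICA-based artifact cleanup (opt-in)
#'
#' Decomposes the recording into independent components and zeroes flagged
#' components before back-projection. With `reject_rule = "none"` (the
#' default) the recording is returned unaltered: data are never silently
#' modified. `"kurtosis_top_k"` flags the `k` components with the highest
#' excess kurtosis (blink/spike-like sources are strongly leptokurtic);
#' `"manual_indices"` flags a user-supplied component index set.
#'
#' @param rec an [eeg_recording()].
#' @param n_components number of components (default: all channels).
#' @param reject_rule `"none"`, `"kurtosis_top_k"` or `"manual_indices"`.
#' @param k number of components rejected under the kurtosis rule.
#' @param indices component indices rejected under the manual rule.
#' @param seed seed for the ICA initialization (deterministic output).
#' @return A cleaned [eeg_recording()].
#' @export
ica_clean <- function(rec, n_components = NULL,
                      reject_rule = c("none", "kurtosis_top_k",
                                      "manual_indices"),
                      k = 1L, indices = NULL, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  reject_rule <- match.arg(reject_rule)
  M <- nrow(rec$data)
  if (is.null(n_components)) n_components <- M
  if (n_components > M)
    stop("n_components (", n_components, ") exceeds channel count (", M, ")")
  if (reject_rule == "none") return(rec)
  fit <- .fastica(rec$data, n_components, seed = seed)
  drop <- switch(reject_rule,
    kurtosis_top_k = {
      kk <- apply(fit$S, 1L, function(s) {
        m2 <- mean((s - mean(s))^2)
        if (m2 < 1e-24) return(-Inf)
        mean((s - mean(s))^4) / m2^2 - 3
      })
      order(kk, decreasing = TRUE)[seq_len(min(k, n_components))]
    },
    manual_indices = {
      if (is.null(indices)) stop("manual_indices rule requires 'indices'")
      indices <- as.integer(indices)
      if (any(indices < 1L | indices > n_components))
        stop("component indices out of range 1..", n_components)
      indices
    })
  S <- fit$S
  S[drop, ] <- 0
  out <- rec
  out$data <- fit$A %*% S + fit$mean
  out
}

#' Sliding-window segmentation within state blocks
#'
#' Cuts fixed-length windows independently inside each annotated state
#' block, after discarding the block's first `drop_initial_s` seconds.
#' Windows never cross block boundaries, so every segment carries an
#' unambiguous state label. Per block of duration `T`, the number of
#' segments is `floor((T - drop - window)/step) + 1` (0 when negative).
#'
#' @param rec an annotated [eeg_recording()].
#' @param cfg a [segmentation_config()].
#' @return List of segments; each is a list with `data`
#'   (n_channels x n_window), `fs`, `state_label`, `subject_id`,
#'   `session_id`, `t_start_s` and class `"eeg_segment"`.
#' @export
segment_sliding <- function(rec, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(cfg, "segmentation_config"))
  if (nrow(rec$annotations) < 1L)
    stop("recording has no state annotations to segment")
  n_win <- as.integer(round(cfg$window_s * rec$fs))
  out <- list()
  for (b in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[b, ]
    t0 <- a$start_s + cfg$drop_initial_s
    avail <- a$end_s - t0
    n_seg <- if (avail >= cfg$window_s)
      floor((avail - cfg$window_s) / cfg$step_s + 1e-9) + 1L else 0L
    if (n_seg < 1L) next
    for (s in seq_len(n_seg)) {
      ts <- t0 + (s - 1L) * cfg$step_s
      i0 <- as.integer(round(ts * rec$fs))      # 0-based sample index
      idx <- (i0 + 1L):(i0 + n_win)
      out[[length(out) + 1L]] <- structure(
        list(data = rec$data[, idx, drop = FALSE], fs = rec$fs,
             state_label = a$label, subject_id = rec$subject_id,
             session_id = rec$session_id, t_start_s = ts),
        class = "eeg_segment")
    }
  }
  out
}
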