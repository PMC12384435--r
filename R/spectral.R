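#' Blackman window
#'
#' `w(n) = 0.42 - 0.5 cos(2 pi n/(M-1)) + 0.08 cos(4 pi n/(M-1))` for
#' `n = 0..M-1`. Endpoints are exactly 0 and the centre of an odd-length
#' window is exactly 1.
#'
#' @param M window length in samples (>= 2).
#' @return Numeric vector of length `M`.
#' @export
blackman_window <- function(M) {
  if (M < 2L) stop("window length M must be >= 2")
  n <- 0:(M - 1L)
  0.42 - 0.5 * cos(2 * pi * n / (M - 1L)) + 0.08 * cos(4 * pi * n / (M - 1L))
}

# Mean one-sided power spectrum of one frame: sub-windows of length M
# (hop M/2 when the frame is longer than M), zero-padded to nfft.
.frame_power <- function(x, w, nfft) {
  M <- length(w)
  starts <- if (length(x) == M) 1L else
    unique(c(seq(1L, length(x) - M + 1L, by = max(1L, M %/% 2L)),
             length(x) - M + 1L))
  nb <- nfft %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + M - 1L)] * w
    sp <- stats::fft(c(seg, numeric(nfft - M)))
    acc <- acc + Mod(sp[seq_len(nb)])^2
  }
  acc / length(starts)
}

#' Per-channel STFT dB spectrum of a segment
#'
#' For every channel, power spectrograms are computed on a per-second basis
#' (non-overlapping 1 s frames, Blackman window), averaged over the segment,
#' floored at `db_floor` and converted to `10 log10` decibels. The result is
#' truncated or resampled to exactly `n_bins` bins per channel:
#' when `freq_cap_hz` is `NA` the FFT is zero-padded to `2 (n_bins - 1)`
#' points and the first `n_bins` one-sided bins are kept; otherwise the
#' spectrum is restricted to `[0, freq_cap_hz]` and linearly interpolated
#' onto `n_bins` evenly spaced frequencies so different sampling rates share
#' one feature geometry.
#'
#' @param seg an `"eeg_segment"` (or any list with `data` and `fs`).
#' @param win window weights, e.g. [blackman_window()] (default M = 128).
#' @param n_bins output bins per channel (default 80).
#' @param freq_cap_hz optional frequency cap in Hz (default `NA`).
#' @param db_floor power floor applied before the log (default 1e-12).
#' @return Numeric vector of length `n_channels * n_bins`, channel-major,
#'   with attributes `n_channels` and `n_bins`.
#' @export
stft_db_spectrum <- function(seg, win = blackman_window(128L), n_bins = 80L,
                             freq_cap_hz = NA_real_, db_floor = 1e-12) {
  X <- seg$data; fs <- seg$fs
  M <- length(win)
  if (ncol(X) < M)
    stop("segment (", ncol(X), " samples) shorter than the window (", M, ")")
  frame_len <- as.integer(round(fs))
  n_frames <- max(1L, ncol(X) %/% frame_len)
  nfft <- if (is.na(freq_cap_hz)) max(M, 2L * (n_bins - 1L)) else
    max(512L, 2L * M)
  out <- numeric(nrow(X) * n_bins)
  for (ch in seq_len(nrow(X))) {
    acc <- NULL
    for (f in seq_len(n_frames)) {
      idx <- ((f - 1L) * frame_len + 1L):(f * frame_len)
      if (length(idx) < M) idx <- (ncol(X) - M + 1L):ncol(X)
      p <- .frame_power(X[ch, idx], win, nfft)
      acc <- if (is.null(acc)) p else acc + p
    }
    p <- acc / n_frames
    if (is.na(freq_cap_hz)) {
      pv <- p[seq_len(n_bins)]
    } else {
      freqs <- (seq_along(p) - 1L) * fs / nfft
      keep <- freqs <= freq_cap_hz
      pv <- stats::approx(freqs[keep], p[keep],
                          xout = seq(0, freq_cap_hz, length.out = n_bins),
                          rule = 2)$y
    }
    out[((ch - 1L) * n_bins + 1L):(ch * n_bins)] <-
      10 * log10(pmax(pv, db_floor))
  }
  structure(out, n_channels = nrow(X), n_bins = as.integer(n_bins))
}

#' First-order spectral difference features
#'
#' Differences `d[i] = v[i+1] - v[i]` over the whole concatenated spectral
#' vector (length `L - 1`). Each difference is assigned to the channel group
#' of its right-hand element, so for `C` channels of `B` bins the groups
#' have sizes `B - 1, B, ..., B`.
#'
#' @param sv a spectral vector from [stft_db_spectrum()].
#' @return List with `values` (length `L - 1`) and `group` (channel index of
#'   each difference).
#' @export
diff_features <- function(sv) {
  if (length(sv) < 2L) stop("spectral vector must have length >= 2")
  nc <- attr(sv, "n_channels") %||% 1L
  nb <- attr(sv, "n_bins") %||% length(sv)
  d <- diff(as.numeric(sv))
  group <- ((seq_along(d) + 1L) - 1L) %/% nb + 1L   # channel of right element
  group <- pmin(group, nc)
  list(values = d, group = as.integer(group))
}

#' Zero-crossing count of a difference signal
#'
#' Counts sign changes between strictly opposite signs; zeros are
#' transparent (a crossing is counted when the first nonzero sign after a
#' run of zeros is opposite to the sign before it).
#'
#' @param d numeric vector (e.g. `diff_features()$values`).
#' @return Non-negative integer.
#' @export
zero_crossing_count <- function(d) {
  if (length(d) < 1L) stop("input must have length >= 1")
  s <- sign(d)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}
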