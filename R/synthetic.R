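#' Synthetic EEG session configuration
#'
#' Describes a three-state synthetic session: montage geometry, an ordered
#' block plan of `(state, duration_s)`, a per-state band-power profile, a
#' set of directed VAR couplings active in chosen states, broadband noise
#' and a seed. Defaults emulate the 7-channel, 128 Hz study protocol: three
#' consecutive 600 s blocks (states 0, 1, 2) whose theta/alpha/beta relative
#' amplitudes follow the classic attention physiology (state 0 beta-dominant
#' "focused", state 1 alpha-dominant "unfocused", state 2 theta-dominant
#' "drowsy"), plus one centro-parietal coupling (Cz -> Pz) active in the
#' drowsy state.
#'
#' @param n_channels 7 or 32.
#' @param fs 128 or 500 Hz.
#' @param blocks data.frame with columns `state` (0/1/2) and `duration_s`.
#' @param band_profile 3 x 3 numeric matrix, rows = states 0..2, columns =
#'   theta/alpha/beta relative amplitudes (band power scales as the square).
#' @param couplings data.frame with columns `source`, `target` (1-based
#'   channel indices), `state` (0/1/2), `lag` (samples >= 1) and `gain`
#'   (|gain| < 1), or NULL for none.
#' @param noise_sd broadband white-noise standard deviation (relative to the
#'   unit-variance band oscillators).
#' @param amplitude_uv overall scale in microvolts.
#' @param seed integer seed; identical configs generate identical samples.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_channels = 7L, fs = 128,
                             blocks = data.frame(state = 0:2,
                                                 duration_s = 600),
                             band_profile = default_band_profile(),
                             couplings = default_couplings(n_channels),
                             noise_sd = 0.5, amplitude_uv = 10, seed = 1L) {
  if (!n_channels %in% c(7L, 32L)) stop("n_channels must be 7 or 32")
  if (!fs %in% c(128, 500)) stop("fs must be 128 or 500")
  blocks <- as.data.frame(blocks)
  if (any(blocks$duration_s <= 0)) stop("block durations must be positive")
  if (any(!blocks$state %in% 0:2)) stop("block states must be 0, 1 or 2")
  band_profile <- as.matrix(band_profile)
  if (!all(dim(band_profile) == c(3L, 3L)))
    stop("band_profile must be 3 states x 3 bands")
  if (!is.null(couplings) && nrow(couplings)) {
    couplings <- as.data.frame(couplings)
    need <- c("source", "target", "state", "lag", "gain")
    if (!all(need %in% names(couplings)))
      stop("couplings needs columns ", paste(need, collapse = ", "))
    if (any(couplings$source < 1L | couplings$source > n_channels) ||
        any(couplings$target < 1L | couplings$target > n_channels))
      stop("coupling channel indices must be in 1..", n_channels)
    if (any(couplings$lag < 1L)) stop("coupling lags must be >= 1 sample")
    if (any(abs(couplings$gain) >= 1))
      stop("coupling gain magnitudes must be < 1 for stability")
  } else couplings <- NULL
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 blocks = blocks, band_profile = band_profile,
                 couplings = couplings, noise_sd = noise_sd,
                 amplitude_uv = amplitude_uv, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default per-state band-amplitude profile
#'
#' Rows are states 0..2, columns theta/alpha/beta relative amplitudes:
#' state 0 beta-dominant, state 1 alpha-dominant, state 2 theta-dominant.
#' @return 3 x 3 numeric matrix.
#' @export
default_band_profile <- function() {
  m <- rbind(c(0.6, 0.8, 1.4),
             c(0.9, 1.5, 0.8),
             c(1.6, 1.0, 0.5))
  dimnames(m) <- list(paste0("state", 0:2), c("theta", "alpha", "beta"))
  m
}

#' Default directed couplings for a montage
#'
#' One centro-parietal coupling towards the parietal midline channel,
#' active only in state 2, lag 1 sample, gain 0.5.
#' @param n_channels 7 or 32.
#' @return data.frame of couplings (see [synthetic_config()]).
#' @export
default_couplings <- function(n_channels = 7L) {
  if (n_channels == 7L)
    data.frame(source = 5L, target = 7L, state = 2L, lag = 1L, gain = 0.5)
  else
    data.frame(source = 15L, target = 25L, state = 2L, lag = 1L, gain = 0.5)
}

.coupling_matrices <- function(cfg, state) {
  cp <- cfg$couplings
  if (!is.null(cp)) cp <- cp[cp$state == state, , drop = FALSE]
  if (is.null(cp) || nrow(cp) == 0L) return(NULL)
  p <- max(cp$lag)
  A <- lapply(seq_len(p), function(r) matrix(0, cfg$n_channels, cfg$n_channels))
  for (i in seq_len(nrow(cp)))
    A[[cp$lag[i]]][cp$target[i], cp$source[i]] <-
      A[[cp$lag[i]]][cp$target[i], cp$source[i]] + cp$gain[i]
  A
}

.companion_radius <- function(A) {
  M <- nrow(A[[1L]]); p <- length(A)
  C <- matrix(0, M * p, M * p)
  for (r in seq_len(p)) C[1:M, ((r - 1L) * M + 1L):(r * M)] <- A[[r]]
  if (p > 1L) C[(M + 1L):(M * p), 1:(M * (p - 1L))] <- diag(M * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# Unit-variance band-limited noise: white noise band-limited exactly in the
# frequency domain (no skirt leakage between bands), rescaled to sd 1.
.band_noise <- function(n, band, fs) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)    # two-sided
  sp[freqs < band[1L] | freqs > band[2L]] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate a seeded synthetic EEG session
#'
#' Each state block is built as unit-variance band-limited oscillators
#' (theta/alpha/beta filtered noise) scaled by the state's band-amplitude
#' profile, plus broadband white noise; directed couplings are then applied
#' as a stable VAR recursion (target channels receive lagged source signal),
#' so both the spectral and the connectivity stages of the pipeline have
#' recoverable ground truth. Identical configurations (including the seed)
#' generate bitwise-identical samples.
#'
#' @param cfg a [synthetic_config()].
#' @param subject_id,session_id identifiers stamped on the recording.
#' @return An annotated [eeg_recording()].
#' @export
generate_synthetic_session <- function(cfg, subject_id = "S1",
                                       session_id = "R1") {
  stopifnot(inherits(cfg, "synthetic_config"))
  for (s in unique(cfg$blocks$state)) {
    A <- .coupling_matrices(cfg, s)
    if (!is.null(A) && .companion_radius(A) >= 1)
      stop("unstable coupling spec for state ", s,
           " (companion spectral radius >= 1)")
  }
  labels <- if (cfg$n_channels == 7L) .channels_7 else .channels_32
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  bands <- eeg_bands()
  blocks_x <- vector("list", nrow(cfg$blocks))
  ann <- data.frame(label = integer(0), start_s = numeric(0),
                    end_s = numeric(0))
  t_cursor <- 0
  for (b in seq_len(nrow(cfg$blocks))) {
    state <- cfg$blocks$state[b]
    n <- as.integer(round(cfg$blocks$duration_s[b] * cfg$fs))
    prof <- cfg$band_profile[state + 1L, ]
    innov <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      x <- stats::rnorm(n, sd = cfg$noise_sd)
      for (k in seq_along(bands))
        x <- x + prof[k] * .band_noise(n, bands[[k]], cfg$fs)
      innov[ch, ] <- x
    }
    A <- .coupling_matrices(cfg, state)
    if (is.null(A)) {
      X <- innov
    } else {
      p <- length(A)
      X <- innov
      for (t in (p + 1L):n) {
        acc <- innov[, t]
        for (r in seq_len(p)) acc <- acc + A[[r]] %*% X[, t - r]
        X[, t] <- acc
      }
    }
    blocks_x[[b]] <- X * cfg$amplitude_uv
    ann <- rbind(ann, data.frame(label = state, start_s = t_cursor,
                                 end_s = t_cursor + n / cfg$fs))
    t_cursor <- t_cursor + n / cfg$fs
  }
  eeg_recording(do.call(cbind, blocks_x), cfg$fs, labels,
                subject_id = subject_id, session_id = session_id,
                annotations = ann)
}
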