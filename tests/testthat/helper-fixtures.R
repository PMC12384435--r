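# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# Small three-state 7-channel session: 8 segments per state (52 s blocks,
# default 5 s window / 6 s step / 4 s initial drop).
fixture_session_7ch <- function() {
  if (is.null(.fixture_env$rec7)) {
    cfg <- synthetic_config(blocks = data.frame(state = 0:2,
                                                duration_s = 52),
                            seed = 101L)
    .fixture_env$rec7 <- generate_synthetic_session(cfg)
  }
  .fixture_env$rec7
}

# Its extracted feature table (24 x 1735) with layout and provenance.
fixture_features_7ch <- function() {
  if (is.null(.fixture_env$feat7)) {
    .fixture_env$feat7 <- extract_features(fixture_session_7ch(),
                                           pipeline_config("7ch"),
                                           segmentation_config())
  }
  .fixture_env$feat7
}

# One band-filtered segment triple of the fixture session.
fixture_segment_bands_7ch <- function() {
  if (is.null(.fixture_env$segbands)) {
    rec <- fixture_session_7ch()
    cfg <- pipeline_config("7ch")
    scfg <- segmentation_config()
    filt <- lapply(names(cfg$bands), function(b)
      segment_sliding(bandpass_filter(rec, cfg$bands[[b]]), scfg))
    names(filt) <- names(cfg$bands)
    .fixture_env$segbands <- list(
      raw = segment_sliding(rec, scfg)[[1L]],
      bands = lapply(filt, `[[`, 1L))
  }
  .fixture_env$segbands
}

# Deterministic multi-tone recording for filter/segmentation tests.
tone_recording <- function(freqs = c(10, 20), fs = 128, dur = 12,
                           n_ch = length(freqs), ann = TRUE) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  X <- t(vapply(seq_len(n_ch),
                function(i) sin(2 * pi * freqs[i] * t), numeric(length(t))))
  a <- if (ann) data.frame(label = 0L, start_s = 0, end_s = dur) else NULL
  eeg_recording(X, fs, paste0("ch", seq_len(n_ch)), annotations = a)
}

# Brute-force confusion-matrix metrics oracle (independent of the package).
oracle_metrics <- function(y_true, y_pred) {
  lv <- sort(unique(c(y_true, y_pred)))
  prec <- rec <- f1 <- numeric(length(lv))
  for (i in seq_along(lv)) {
    cl <- lv[i]
    tp <- sum(y_true == cl & y_pred == cl)
    pp <- sum(y_pred == cl); ap <- sum(y_true == cl)
    prec[i] <- if (pp > 0) tp / pp else 0
    rec[i] <- if (ap > 0) tp / ap else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(accuracy = 100 * mean(y_true == y_pred), f1 = 100 * mean(f1),
       recall = 100 * mean(rec), precision = 100 * mean(prec))
}

# Brute-force BFS shortest-path matrix (queue-based, independent of the
# matrix-power implementation).
oracle_bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in which(A[v, ] > 0)) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

# Brute-force graph metrics from BFS distances and triangle loops.
oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_distances(A)
  ge_of <- function(D) {
    n <- nrow(D)
    if (n < 2) return(0)
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
    tot / (n * (n - 1))
  }
  le <- 0
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) >= 2) {
      sub <- A[nb, nb, drop = FALSE]
      le <- le + ge_of(oracle_bfs_distances(sub))
      links <- 0
      for (a in seq_along(nb)) for (b in seq_along(nb))
        if (a < b && sub[a, b] > 0) links <- links + 1
      cc[i] <- 2 * links / (length(nb) * (length(nb) - 1))
    }
  }
  list(global_efficiency = ge_of(D), local_efficiency = le / n,
       mean_clustering = mean(cc), mean_degree = mean(colSums(A)))
}
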