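#' Ten statistical descriptors of a value vector
#'
#' Fixed order: lower quartile, upper quartile, 10% two-sided trimmed mean,
#' minimum, maximum, standard deviation, mean square, skewness, excess
#' kurtosis, and the sum of square roots of absolute values. Quartiles use
#' linear interpolation between order statistics; the trimmed mean drops
#' `floor(0.1 n)` values from each tail; skewness and kurtosis are
#' moment-based and defined as 0 when the variance is 0; the square-root
#' sum uses absolute values because dB features are routinely negative.
#'
#' @param v non-empty numeric vector.
#' @return Named numeric vector of length 10.
#' @export
stat_descriptors <- function(v) {
  if (length(v) == 0L) stop("cannot compute descriptors of an empty vector")
  n <- length(v)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 < 1e-24) {
    skw <- 0; kur <- 0
  } else {
    skw <- mean((v - m)^3) / m2^1.5
    kur <- mean((v - m)^4) / m2^2 - 3
  }
  c(q1 = q[1L], q3 = q[2L],
    trimmed_mean = mean(v, trim = 0.1),
    min = min(v), max = max(v),
    sd = if (n > 1L) stats::sd(v) else 0,
    mean_square = mean(v^2),
    skewness = skw, kurtosis = kur,
    sum_sqrt = sum(sqrt(abs(v))))
}

# ---- feature layout ----------------------------------------------------

#' Feature-vector layout for a montage
#'
#' Ordered, contiguous named blocks of the assembled per-segment vector:
#' per-channel STFT spectra, per-channel spectral differences, the group
#' statistics, the zero-crossing count, the per-(band, metric) graph
#' descriptors and the per-(band, metric) upper-triangular connectivity
#' values. Totals 1735 for the 7-channel montage and 13,735 for the
#' 32-channel montage.
#'
#' @param config an [pipeline_config()].
#' @return Object of class `"feature_layout"` with `blocks`
#'   (data.frame `name`, `start`, `length`) and `montage`.
#' @export
feature_layout <- function(config) {
  C <- config$n_channels
  nb <- config$n_bins
  M <- C
  gl <- graph_descriptor_length(config)
  ut <- M * (M - 1L) / 2L
  bands <- names(config$bands)
  nm <- c(paste0("stft_", config$channel_labels),
          paste0("diff_", config$channel_labels),
          "group_stats", "zero_crossing",
          as.vector(t(outer(bands, config$metrics,
                            function(b, m) paste0("graph_", b, "_", m)))),
          as.vector(t(outer(bands, config$metrics,
                            function(b, m) paste0("conn_", b, "_", m)))))
  len <- c(rep(nb, C),
           c(nb - 1L, rep(nb, C - 1L)),
           10L * (1L + 2L * C), 1L,
           rep(gl, length(bands) * length(config$metrics)),
           rep(ut, length(bands) * length(config$metrics)))
  feature_layout_from_blocks(
    data.frame(name = nm, start = cumsum(c(1L, len[-length(len)])),
               length = len, stringsAsFactors = FALSE),
    config$montage)
}

#' Build a layout from an explicit block table
#' @param blocks data.frame with columns `name`, `start`, `length`
#'   (contiguous, 1-based).
#' @param montage montage id string.
#' @return A `"feature_layout"`.
#' @export
feature_layout_from_blocks <- function(blocks, montage) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("name", "start", "length") %in% names(blocks)))
  blocks$start <- as.integer(blocks$start)
  blocks$length <- as.integer(blocks$length)
  if (nrow(blocks) > 1L &&
      any(blocks$start[-1L] != (blocks$start + blocks$length)[-nrow(blocks)]))
    stop("layout blocks must be contiguous")
  structure(list(blocks = blocks, montage = montage),
            class = "feature_layout")
}

#' Total length of a feature layout
#' @param layout a [feature_layout()].
#' @return integer.
#' @export
layout_total <- function(layout) sum(layout$blocks$length)

#' Column indices of one or more layout blocks
#' @param layout a [feature_layout()].
#' @param pattern regular expression matched against block names.
#' @return Integer vector of column indices (in layout order).
#' @export
layout_indices <- function(layout, pattern) {
  b <- layout$blocks
  hit <- grepl(pattern, b$name)
  if (!any(hit)) stop("no layout block matches '", pattern, "'")
  unlist(lapply(which(hit), function(i)
    seq.int(b$start[i], length.out = b$length[i])), use.names = FALSE)
}

#' @export
print.feature_layout <- function(x, ...) {
  cat("Feature layout (", x$montage, "): ", nrow(x$blocks), " blocks, ",
      layout_total(x), " features\n", sep = "")
  invisible(x)
}

# ---- grouping and assembly ---------------------------------------------

#' Organize features into statistic groups
#'
#' One group for all upper-triangular connectivity values, one per channel
#' for the raw STFT spectra and one per channel for the difference
#' features: `1 + 2 C` groups (15 for 7 channels, 65 for 32), each of which
#' feeds [stat_descriptors()].
#'
#' @param sv spectral vector ([stft_db_spectrum()]).
#' @param d difference features ([diff_features()]).
#' @param tensor_upper concatenated upper-triangular connectivity values.
#' @param config an [pipeline_config()].
#' @return Named list of numeric vectors.
#' @export
group_features <- function(sv, d, tensor_upper, config) {
  C <- config$n_channels
  nb <- config$n_bins
  if (length(sv) != C * nb)
    stop("spectral vector length ", length(sv), " != ", C * nb)
  if (length(d$values) != C * nb - 1L)
    stop("difference vector length ", length(d$values), " != ", C * nb - 1L)
  ut <- C * (C - 1L) / 2L * length(config$bands) * length(config$metrics)
  if (length(tensor_upper) != ut)
    stop("connectivity value vector length ", length(tensor_upper),
         " != ", ut)
  groups <- list(connectivity = as.numeric(tensor_upper))
  for (ch in seq_len(C))
    groups[[paste0("stft_", config$channel_labels[ch])]] <-
      as.numeric(sv[((ch - 1L) * nb + 1L):(ch * nb)])
  for (ch in seq_len(C))
    groups[[paste0("diff_", config$channel_labels[ch])]] <-
      d$values[d$group == ch]
  groups
}

#' Assemble the consolidated per-segment feature vector
#'
#' Concatenation in layout order: raw STFT spectra, spectral differences,
#' group statistics, the zero-crossing count, graph descriptors, and raw
#' upper-triangular connectivity values. Totals
#' `560 + 559 + 150 + 1 + 150 + 315 = 1735` (7 channels) and
#' `2560 + 2559 + 650 + 1 + 525 + 7440 = 13,735` (32 channels).
#'
#' @param sv spectral vector.
#' @param d difference features (list from [diff_features()]).
#' @param zc zero-crossing count (scalar).
#' @param graph_desc concatenated graph descriptors (band-major, metric
#'   within band).
#' @param upper concatenated upper-triangular values (same order).
#' @param stats concatenated group statistics (10 per group).
#' @param config an [pipeline_config()].
#' @return Numeric vector of length `layout_total(feature_layout(config))`.
#' @export
assemble_feature_vector <- function(sv, d, zc, graph_desc, upper, stats,
                                    config) {
  layout <- feature_layout(config)
  C <- config$n_channels
  parts <- list(stft = as.numeric(sv), diff = as.numeric(d$values),
                stats = as.numeric(stats), zero_crossing = as.numeric(zc),
                graph = as.numeric(graph_desc), upper = as.numeric(upper))
  want <- c(stft = C * config$n_bins, diff = C * config$n_bins - 1L,
            stats = 10L * (1L + 2L * C), zero_crossing = 1L,
            graph = graph_descriptor_length(config) * 3L * 5L,
            upper = C * (C - 1L) / 2L * 15L)
  for (nm in names(parts))
    if (length(parts[[nm]]) != want[[nm]])
      stop("block '", nm, "' has length ", length(parts[[nm]]),
           ", expected ", want[[nm]])
  out <- c(parts$stft, parts$diff, parts$stats, parts$zero_crossing,
           parts$graph, parts$upper)
  stopifnot(length(out) == layout_total(layout))
  out
}

# ---- isolation forest --------------------------------------------------

.iforest_cn <- function(n) {
  if (n <= 1) 0 else if (n == 2) 1 else
    2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

.itree_build <- function(X, idx, depth, limit) {
  if (depth >= limit || length(idx) <= 1L)
    return(list(leaf = TRUE, size = length(idx)))
  sub <- X[idx, , drop = FALSE]
  rng <- apply(sub, 2L, range)
  ok <- which(rng[2L, ] - rng[1L, ] > 1e-24)
  if (!length(ok)) return(list(leaf = TRUE, size = length(idx)))
  q <- ok[sample.int(length(ok), 1L)]
  p <- stats::runif(1L, rng[1L, q], rng[2L, q])
  left <- idx[X[idx, q] < p]
  right <- idx[X[idx, q] >= p]
  list(leaf = FALSE, q = q, p = p,
       left = .itree_build(X, left, depth + 1L, limit),
       right = .itree_build(X, right, depth + 1L, limit))
}

.itree_path <- function(node, x, depth = 0) {
  while (!node$leaf) {
    node <- if (x[node$q] < node$p) node$left else node$right
    depth <- depth + 1
  }
  depth + .iforest_cn(node$size)
}

.iforest_scores <- function(trees, psi, X) {
  cn <- .iforest_cn(psi)
  vapply(seq_len(nrow(X)), function(i) {
    e <- mean(vapply(trees, .itree_path, 0, x = X[i, ]))
    2^(-e / cn)
  }, 0)
}

#' Isolation-forest outlier mask
#'
#' Fits an isolation forest (random binary partition trees on subsamples;
#' anomalies isolate in few splits) on the training rows and masks the
#' `floor(contamination * n)` rows with the highest anomaly scores. The
#' fitted detector can score held-out rows without refitting via
#' [iforest_score()].
#'
#' @param x numeric matrix with >= 10 rows (training rows only).
#' @param contamination expected outlier fraction in `[0, 0.5)`.
#' @param n_trees number of trees (default 100).
#' @param sample_size per-tree subsample size (default `min(256, n)`).
#' @param seed integer seed (deterministic mask).
#' @return List with `keep` (logical inlier mask), `scores`, and
#'   `detector` (class `"iforest"`).
#' @export
isolation_outlier_mask <- function(x, contamination = 0.02, n_trees = 100L,
                                   sample_size = NULL, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 rows to fit the detector")
  if (contamination < 0 || contamination >= 0.5)
    stop("contamination must be in [0, 0.5)")
  psi <- as.integer(min(sample_size %||% 256L, n))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  limit <- ceiling(log2(psi))
  trees <- lapply(seq_len(n_trees), function(t)
    .itree_build(x, sample.int(n, psi), 0L, limit))
  det <- structure(list(trees = trees, psi = psi), class = "iforest")
  scores <- .iforest_scores(trees, psi, x)
  n_out <- floor(contamination * n + 1e-9)
  keep <- rep(TRUE, n)
  if (n_out > 0L) {
    keep[order(scores, decreasing = TRUE)[seq_len(n_out)]] <- FALSE
    det$threshold <- min(scores[!keep])
  } else det$threshold <- Inf
  list(keep = keep, scores = scores, detector = det)
}

#' Score rows with a fitted isolation forest
#' @param detector an `"iforest"` from [isolation_outlier_mask()].
#' @param x numeric matrix of rows to score.
#' @return Anomaly scores in `(0, 1)`; higher = more anomalous.
#' @export
iforest_score <- function(detector, x) {
  stopifnot(inherits(detector, "iforest"))
  .iforest_scores(detector$trees, detector$psi, as.matrix(x))
}
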