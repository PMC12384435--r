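#' Canonical EEG frequency bands
#'
#' Returns the three wakefulness bands used throughout the pipeline:
#' theta (4--8 Hz), alpha (8--12 Hz) and beta (12--30 Hz).
#'
#' @return Named list of length-2 numeric vectors `c(lo_hz, hi_hz)`.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

#' Connectivity metrics computed per band
#' @return Character vector in canonical order.
#' @export
connectivity_metrics <- function() c("PLV", "PLI", "S", "GC", "PDC")

.channels_7 <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "Pz")

.channels_32 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FT7", "FC3", "FCz", "FC4", "FT8",
  "T7", "C3", "Cz", "C4", "T8",
  "TP7", "CP3", "CPz", "CP4", "TP8",
  "P7", "P3", "Pz", "P4", "P8",
  "PO3", "POz", "PO4", "O1", "O2"
)

# Scalar graph descriptors aggregated across thresholds ({sum, mean} each).
.menu_7ch <- c(
  "global_efficiency", "local_efficiency", "mean_clustering",
  "mean_degree", "max_degree"
)

.menu_32ch <- c(
  "global_efficiency", "local_efficiency", "mean_clustering",
  "mean_degree", "max_degree", "degree_variance", "edge_density",
  "transitivity", "n_components", "largest_component_fraction",
  "assortativity", "mean_betweenness", "max_betweenness",
  "mean_closeness", "diameter_largest", "mean_eccentricity_largest",
  "isolated_count"
)

#' Pipeline configuration for a montage
#'
#' Bundles every tunable of the feature pipeline for one of the two
#' supported montages: a 7-channel frontal/central/parietal layout sampled
#' at 128 Hz, or a dense 32-channel 10-10 layout at 500 Hz. All defaults
#' can be overridden via `...`.
#'
#' @param montage `"7ch"` or `"32ch"`.
#' @param ... overrides for any configuration field (e.g. `mar_order = 8`).
#' @return List of class `"attn_config"` with fields:
#'   \describe{
#'     \item{n_channels, fs, channel_labels}{montage geometry}
#'     \item{bands}{see [eeg_bands()]}
#'     \item{metrics}{see [connectivity_metrics()]}
#'     \item{stft_window, n_bins, freq_cap_hz, db_floor}{spectral stage}
#'     \item{n_thresholds, graph_menu, graph_connected_count}{network stage}
#'     \item{mar_order, pdc_n_freqs, s_index}{connectivity estimators}
#'   }
#' @export
pipeline_config <- function(montage = c("7ch", "32ch"), ...) {
  montage <- match.arg(montage)
  cfg <- if (montage == "7ch") {
    list(
      montage = "7ch",
      n_channels = 7L,
      fs = 128,
      channel_labels = .channels_7,
      bands = eeg_bands(),
      metrics = connectivity_metrics(),
      stft_window = 128L,
      n_bins = 80L,
      freq_cap_hz = NA_real_,   # keep the first n_bins FFT bins as-is
      db_floor = 1e-12,
      n_thresholds = 130L,
      graph_menu = .menu_7ch,
      graph_connected_count = FALSE,
      mar_order = 5L,
      pdc_n_freqs = 20L,
      s_index = list(d = 3L, tau = 1L, k = 4L, max_ref = 128L)
    )
  } else {
    list(
      montage = "32ch",
      n_channels = 32L,
      fs = 500,
      channel_labels = .channels_32,
      bands = eeg_bands(),
      metrics = connectivity_metrics(),
      stft_window = 128L,
      n_bins = 80L,
      freq_cap_hz = 40,         # restrict to 0-40 Hz, resampled to n_bins
      db_floor = 1e-12,
      n_thresholds = 130L,
      graph_menu = .menu_32ch,
      graph_connected_count = TRUE,
      mar_order = 5L,
      pdc_n_freqs = 20L,
      s_index = list(d = 3L, tau = 1L, k = 4L, max_ref = 128L)
    )
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown pipeline_config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg$n_channels <- as.integer(cfg$n_channels)
  if (length(cfg$channel_labels) != cfg$n_channels)
    stop("channel_labels length must equal n_channels")
  structure(cfg, class = "attn_config")
}

#' Number of graph descriptors per connectivity matrix
#' @param config an [pipeline_config()] object.
#' @return Integer: 10 for the 7-channel menu, 35 for the 32-channel menu.
#' @export
graph_descriptor_length <- function(config) {
  2L * length(config$graph_menu) + as.integer(isTRUE(config$graph_connected_count))
}

#' @export
print.attn_config <- function(x, ...) {
  cat("attnstate pipeline configuration (", x$montage, ")\n", sep = "")
  cat("  channels : ", x$n_channels, " @ ", x$fs, " Hz\n", sep = "")
  cat("  bands    : ", paste(names(x$bands), collapse = ", "), "\n", sep = "")
  cat("  metrics  : ", paste(x$metrics, collapse = ", "), "\n", sep = "")
  cat("  spectral : ", x$n_bins, " bins, window ", x$stft_window, "\n", sep = "")
  cat("  network  : ", x$n_thresholds, " thresholds, ",
      graph_descriptor_length(x), " descriptors/matrix\n", sep = "")
  invisible(x)
}
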