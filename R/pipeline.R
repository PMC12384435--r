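#' Feature vector of one segment
#'
#' Runs the full per-segment feature pipeline: STFT dB spectrum and
#' differences on the broadband data, the 15-matrix connectivity tensor on
#' the band-filtered data, threshold-profile graph descriptors (GC min-max
#' rescaled to the unit interval first), upper-triangular connectivity
#' values, group statistics and the zero-crossing count, assembled in
#' layout order.
#'
#' @param seg broadband `"eeg_segment"`.
#' @param seg_by_band named list of band-filtered versions of the same
#'   segment.
#' @param config an [pipeline_config()].
#' @return Numeric feature vector (1735 or 13,735 long).
#' @export
segment_features <- function(seg, seg_by_band, config) {
  sv <- stft_db_spectrum(seg, blackman_window(config$stft_window),
                         n_bins = config$n_bins,
                         freq_cap_hz = config$freq_cap_hz,
                         db_floor = config$db_floor)
  d <- diff_features(sv)
  zc <- zero_crossing_count(d$values)
  tensor <- connectivity_tensor(seg_by_band, config)
  graph_desc <- numeric(0)
  upper <- numeric(0)
  for (b in names(config$bands)) for (m in config$metrics) {
    W <- tensor$matrices[[paste0(m, ".", b)]]
    Wt <- if (m == "GC") rescale_unit(W) else pmin(pmax(W, 0), 1)
    graph_desc <- c(graph_desc,
                    threshold_profile(Wt, config$n_thresholds,
                                      menu = config$graph_menu,
                                      connected_count =
                                        config$graph_connected_count))
    upper <- c(upper, upper_triangle(W))
  }
  groups <- group_features(sv, d, upper, config)
  stats <- unlist(lapply(groups, stat_descriptors), use.names = FALSE)
  assemble_feature_vector(sv, d, zc, graph_desc, upper, stats, config)
}

#' Extract the feature table of a recording
#'
#' Band-filters the recording into theta/alpha/beta, segments each version
#' with identical windows and computes [segment_features()] per segment.
#'
#' @param rec an annotated [eeg_recording()].
#' @param config an [pipeline_config()].
#' @param seg_cfg a [segmentation_config()].
#' @param verbose print progress every 50 segments?
#' @return List with `x` (segments x features matrix), `layout`, and
#'   `meta` (data.frame `subject`, `session`, `t_start`, `label`).
#' @export
extract_features <- function(rec, config = pipeline_config("7ch"),
                             seg_cfg = segmentation_config(),
                             verbose = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  filtered <- lapply(names(config$bands), function(b)
    bandpass_filter(rec, config$bands[[b]]))
  names(filtered) <- names(config$bands)
  segs <- segment_sliding(rec, seg_cfg)
  segs_band <- lapply(filtered, segment_sliding, cfg = seg_cfg)
  layout <- feature_layout(config)
  n <- length(segs)
  x <- matrix(0, n, layout_total(layout))
  for (i in seq_len(n)) {
    sb <- lapply(segs_band, `[[`, i)
    x[i, ] <- segment_features(segs[[i]], sb, config)
    if (verbose && i %% 50L == 0L)
      message("  segment ", i, "/", n)
  }
  meta <- data.frame(
    subject = vapply(segs, `[[`, "", "subject_id"),
    session = vapply(segs, `[[`, "", "session_id"),
    t_start = vapply(segs, `[[`, 0, "t_start_s"),
    label = vapply(segs, `[[`, 0L, "state_label"))
  list(x = x, layout = layout, meta = meta)
}

#' Fit the attention-state classifier
#'
#' The trainable stage of the pipeline as one model: optional
#' isolation-forest outlier masking, the two-stage feature selection
#' ([fit_selection()]) and the grid-searched RBF SVM ([svm_train()]), all
#' fitted on the supplied training rows only.
#'
#' @param x assembled feature matrix (training rows).
#' @param y labels 0/1/2.
#' @param layout the matching [feature_layout()].
#' @param config an [pipeline_config()].
#' @param contamination isolation-forest contamination; 0 (default)
#'   disables outlier masking.
#' @param top_k selected feature count (default 45).
#' @param rf_seed random-forest seed (default 34).
#' @param svm_seed CV fold seed (default 1).
#' @return Object of class `"attn_model"`.
#' @export
fit_attention_classifier <- function(x, y, layout, config,
                                     contamination = 0, top_k = 45L,
                                     rf_seed = 34L, svm_seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  detector <- NULL
  keep <- rep(TRUE, nrow(x))
  if (contamination > 0) {
    om <- isolation_outlier_mask(x, contamination, seed = rf_seed)
    keep <- om$keep
    detector <- om$detector
  }
  sel <- fit_selection(x[keep, , drop = FALSE], y[keep], layout, config,
                       top_k = top_k, rf_seed = rf_seed)
  xs <- apply_selection(sel, x[keep, , drop = FALSE])
  svm <- svm_train(xs, y[keep], seed = svm_seed)
  structure(list(selection = sel, svm = svm, detector = detector,
                 keep = keep, config_montage = config$montage,
                 classes = sort(unique(y))),
            class = "attn_model")
}

#' @export
predict.attn_model <- function(object, newdata, ...) {
  xs <- apply_selection(object$selection, as.matrix(newdata))
  as.integer(predict(object$svm, xs))
}

#' @export
print.attn_model <- function(x, ...) {
  cat("Attention-state classifier (", x$config_montage, " montage)\n",
      sep = "")
  cat("  classes : ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  features: ", x$selection$top_k, " of ",
      x$selection$n_combined, " stage-2 columns\n", sep = "")
  cat("  SVM     : RBF, C = ", x$svm$cost, ", gamma = ",
      signif(x$svm$gamma, 4), " (CV accuracy ",
      round(100 * x$svm$cv_accuracy, 2), "%)\n", sep = "")
  if (!is.null(x$detector))
    cat("  outliers: ", sum(!x$keep), " training rows masked\n", sep = "")
  invisible(x)
}

#' @export
summary.attn_model <- function(object, ...) {
  print(object)
  cat("\nSelection detail:\n")
  print(object$selection)
  invisible(object)
}

#' @export
plot.attn_model <- function(x, n = 20L, ...) {
  imp <- x$selection$importance
  ord <- order(imp, decreasing = TRUE)[seq_len(min(n, length(imp)))]
  graphics::barplot(rev(imp[ord]), horiz = TRUE,
                    names.arg = rev(paste0("f", ord)), las = 1,
                    xlab = "mean decrease in Gini",
                    main = "Random-forest feature importances", ...)
  invisible(x)
}

#' Evaluate the pipeline under a validation protocol
#'
#' Splits the samples per the protocol, fits the classifier on each fold's
#' training rows (selection and SVM refitted per fold; nothing leaks from
#' test rows) and aggregates fold metrics.
#'
#' @param x assembled feature matrix.
#' @param meta provenance data.frame (`subject`, `session`, `t_start`,
#'   `label`).
#' @param layout the matching [feature_layout()].
#' @param config an [pipeline_config()].
#' @param spec a [protocol_spec()].
#' @param ... passed to [fit_attention_classifier()].
#' @return Object of class `"attn_eval"`: per-fold metrics, aggregate
#'   means, pooled confusion matrix and the protocol spec.
#' @export
evaluate_protocol <- function(x, meta, layout, config,
                              spec = protocol_spec("intra_subject"), ...) {
  folds <- split_protocol(meta, spec)
  per_fold <- list()
  confusion <- NULL
  for (f in folds) {
    if (!length(f$train) || !length(f$test)) next
    model <- fit_attention_classifier(x[f$train, , drop = FALSE],
                                      meta$label[f$train], layout, config,
                                      ...)
    pred <- predict(model, x[f$test, , drop = FALSE])
    m <- compute_metrics(meta$label[f$test], pred)
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f$id, n_test = length(f$test),
                 accuracy = m$accuracy, f1 = m$f1, recall = m$recall,
                 precision = m$precision)
    confusion <- if (is.null(confusion)) m$confusion else
      confusion + m$confusion
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    per_fold = per_fold,
    aggregate = colMeans(per_fold[, c("accuracy", "f1", "recall",
                                      "precision")]),
    confusion = confusion, spec = spec),
    class = "attn_eval")
}

#' @export
print.attn_eval <- function(x, ...) {
  cat("Protocol evaluation: ", x$spec$kind, " (", nrow(x$per_fold),
      " folds)\n", sep = "")
  agg <- round(x$aggregate, 2)
  cat("  accuracy ", agg["accuracy"], "%  F1 ", agg["f1"],
      "  recall ", agg["recall"], "  precision ", agg["precision"], "\n",
      sep = "")
  invisible(x)
}
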