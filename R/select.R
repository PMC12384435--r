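#' Feature subsets for stage-1 LDA projection
#'
#' The per-band raw connectivity value blocks (one subset per band, all
#' five metrics' upper-triangular values), the per-channel STFT blocks and
#' the per-channel difference blocks: `3 + C + C` subsets (17 for 7
#' channels, 67 for 32). Subsets are disjoint index sets into the assembled
#' feature vector.
#'
#' @param layout a [feature_layout()].
#' @param config an [pipeline_config()].
#' @return Named list of integer index vectors.
#' @export
make_subsets <- function(layout, config) {
  if (!identical(layout$montage, config$montage))
    stop("layout montage '", layout$montage, "' does not match config '",
         config$montage, "'")
  subsets <- list()
  for (b in names(config$bands))
    subsets[[paste0("conn_", b)]] <-
      layout_indices(layout, paste0("^conn_", b, "_"))
  for (ch in config$channel_labels)
    subsets[[paste0("stft_", ch)]] <-
      layout_indices(layout, paste0("^stft_", ch, "$"))
  for (ch in config$channel_labels)
    subsets[[paste0("diff_", ch)]] <-
      layout_indices(layout, paste0("^diff_", ch, "$"))
  subsets
}

# Two-discriminant LDA basis via the generalized eigenproblem
# Sw^-1 Sb with a trace-scaled ridge on the within-class scatter, so
# collinear subsets stay solvable.
.lda_basis <- function(X, y, n_comp = 2L, ridge = 1e-6) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < n_comp + 1L)
    stop("need at least ", n_comp + 1L, " classes in the training labels")
  p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2L, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  lam <- ridge * max(sum(diag(Sw)) / p, 1e-12)
  eg <- eigen(solve(Sw + diag(lam, p), Sb))
  V <- Re(eg$vectors[, seq_len(n_comp), drop = FALSE])
  # fix sign for determinism: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(mean = mu, V = V)
}

#' Fit per-subset 2D LDA projections
#'
#' Each subset is independently projected onto its two leading linear
#' discriminants (fitted on training rows only); the projections are
#' concatenated in subset order, giving `2 * n_subsets` columns (34 for 17
#' subsets, 134 for 67).
#'
#' @param x training feature matrix.
#' @param y training labels (3 classes required).
#' @param subsets list of column index vectors ([make_subsets()]).
#' @param ridge trace-scaled ridge added to the within-class scatter.
#' @return List with `bases` (per-subset LDA bases) and `projected`
#'   (n x 2 n_subsets matrix).
#' @export
lda_project_subsets <- function(x, y, subsets, ridge = 1e-6) {
  x <- as.matrix(x)
  bases <- lapply(subsets, function(idx)
    .lda_basis(x[, idx, drop = FALSE], y, ridge = ridge))
  projected <- lda_apply_subsets(bases, subsets, x)
  list(bases = bases, projected = projected)
}

#' Apply fitted subset LDA bases to a feature matrix
#' @param bases fitted bases from [lda_project_subsets()].
#' @param subsets the index sets used at fit time.
#' @param x feature matrix (any rows).
#' @return n x (2 n_subsets) matrix.
#' @export
lda_apply_subsets <- function(bases, subsets, x) {
  x <- as.matrix(x)
  cols <- lapply(seq_along(subsets), function(i) {
    b <- bases[[i]]
    sweep(x[, subsets[[i]], drop = FALSE], 2L, b$mean) %*% b$V
  })
  do.call(cbind, cols)
}

#' Fit / apply z-score standardization
#'
#' Column means and standard deviations are computed from training rows
#' only; zero-variance columns map to 0 (no division error).
#'
#' @param x training matrix (>= 2 rows).
#' @return A scaler (list `mean`, `sd`).
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to fit a scaler")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  list(mean = mu, sd = sd)
}

#' @rdname zscore_fit
#' @param scaler a fitted scaler.
#' @param newx matrix transformed with the training statistics.
#' @return Standardized matrix.
#' @export
zscore_apply <- function(scaler, newx) {
  newx <- as.matrix(newx)
  s <- ifelse(scaler$sd < 1e-15, 1, scaler$sd)
  out <- sweep(sweep(newx, 2L, scaler$mean), 2L, s, "/")
  out[, scaler$sd < 1e-15] <- 0
  out
}

#' Greedy correlation pruning
#'
#' Left-to-right scan: a column is dropped iff its absolute Pearson
#' correlation with an already-kept column exceeds the threshold.
#' Degenerate (zero-variance) columns correlate as 0 by convention.
#' Deterministic keep-first-in-layout-order rule.
#'
#' @param x standardized matrix (>= 2 rows).
#' @param threshold absolute-correlation cutoff (default 0.9).
#' @return Integer vector of kept column indices.
#' @export
correlation_prune <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to compute correlations")
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(x))
  R[!is.finite(R)] <- 0
  kept <- integer(0)
  for (j in seq_len(p)) {
    if (length(kept) && sds[j] > 0 &&
        any(abs(R[j, kept]) > threshold)) next
    kept <- c(kept, j)
  }
  kept
}

#' Random-forest feature ranking
#'
#' Impurity-based (mean decrease in Gini) importances from a
#' 100-tree random forest with `mtry = floor(sqrt(p))`; returns the
#' `top_k` column indices sorted by decreasing importance, ties broken by
#' lower index. Deterministic for a fixed seed.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_estimators number of trees (default 100).
#' @param top_k number of features returned (default 45).
#' @param seed RNG seed (default 34).
#' @return List with `top` (ordered indices, length `top_k`) and
#'   `importance` (all columns).
#' @export
rf_rank_select <- function(x, y, n_estimators = 100L, top_k = 45L,
                           seed = 34L) {
  x <- as.matrix(x)
  if (top_k > ncol(x))
    stop("top_k (", top_k, ") exceeds column count (", ncol(x), ")")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- randomForest::randomForest(x, factor(y), ntree = n_estimators,
                                    mtry = max(1L, floor(sqrt(ncol(x)))))
  imp <- as.numeric(fit$importance[, "MeanDecreaseGini"])
  ord <- order(-imp, seq_along(imp))
  list(top = ord[seq_len(top_k)], importance = imp)
}

#' Fit the two-stage feature-selection model
#'
#' Stage 1: the raw connectivity / STFT / difference subsets are each
#' projected to two linear discriminants. Stage 2: the projections are
#' concatenated with the group statistics, the graph descriptors excluding
#' the PLI-derived ones (dropped for low inter-class variance) and the
#' zero-crossing feature (305 columns for 7 channels, 1205 for 32);
#' the combined matrix is z-scored, pruned at `|r| > 0.9` and ranked by a
#' random forest, keeping the top 45 features. Every fitted quantity comes
#' from training rows only; [apply_selection()] never refits.
#'
#' @param x training feature matrix (assembled vectors).
#' @param y training labels (0/1/2).
#' @param layout the matching [feature_layout()].
#' @param config an [pipeline_config()].
#' @param cor_threshold correlation-pruning cutoff (default 0.9).
#' @param top_k final feature count (default 45).
#' @param rf_seed random-forest seed (default 34).
#' @return Object of class `"selection_model"`.
#' @export
fit_selection <- function(x, y, layout, config, cor_threshold = 0.9,
                          top_k = 45L, rf_seed = 34L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  subsets <- make_subsets(layout, config)
  st1 <- lda_project_subsets(x, y, subsets)
  stage2_idx <- .stage2_indices(layout)
  combined <- cbind(st1$projected, x[, stage2_idx, drop = FALSE])
  scaler <- zscore_fit(combined)
  z <- zscore_apply(scaler, combined)
  kept <- correlation_prune(z, cor_threshold)
  rk <- rf_rank_select(z[, kept, drop = FALSE], y, top_k = top_k,
                       seed = rf_seed)
  structure(list(subsets = subsets, bases = st1$bases,
                 stage2_idx = stage2_idx, scaler = scaler, kept = kept,
                 importance = rk$importance, top = rk$top,
                 n_fit = nrow(x), n_combined = ncol(combined),
                 top_k = top_k),
            class = "selection_model")
}

# Stage-2 passthrough columns: group statistics, graph descriptors minus
# the PLI-derived blocks, and the zero-crossing count.
.stage2_indices <- function(layout) {
  c(layout_indices(layout, "^group_stats$"),
    setdiff(layout_indices(layout, "^graph_"),
            layout_indices(layout, "^graph_.*_PLI$")),
    layout_indices(layout, "^zero_crossing$"))
}

#' Number of stage-2 combined columns of a selection model
#' @param model a `"selection_model"`.
#' @return integer (305 or 1205 for the standard montages).
#' @export
stage2_ncol <- function(model) model$n_combined

#' Apply a fitted selection model
#'
#' Projects new rows through the stored LDA bases, concatenates the
#' stage-2 passthrough columns, standardizes with the training scaler and
#' returns the stored top-k columns. No quantity is refitted.
#'
#' @param model a fitted [fit_selection()] model.
#' @param x feature matrix (assembled vectors, any rows).
#' @return n x top_k matrix.
#' @export
apply_selection <- function(model, x) {
  stopifnot(inherits(model, "selection_model"))
  x <- as.matrix(x)
  proj <- lda_apply_subsets(model$bases, model$subsets, x)
  combined <- cbind(proj, x[, model$stage2_idx, drop = FALSE])
  z <- zscore_apply(model$scaler, combined)
  z[, model$kept, drop = FALSE][, model$top, drop = FALSE]
}

#' @export
print.selection_model <- function(x, ...) {
  cat("Two-stage selection model\n")
  cat("  subsets        : ", length(x$subsets), " (",
      2L * length(x$subsets), " LDA columns)\n", sep = "")
  cat("  stage-2 columns: ", x$n_combined, "\n", sep = "")
  cat("  after pruning  : ", length(x$kept), "\n", sep = "")
  cat("  selected       : ", x$top_k, "\n", sep = "")
  cat("  fitted on      : ", x$n_fit, " rows\n", sep = "")
  invisible(x)
}
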