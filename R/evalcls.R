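#' Validation protocol specification
#'
#' @param kind one of `"intra_subject"` (per-subject random 80/20),
#'   `"pooled_inter_subject"` (pooled random 80/20), `"loso"`
#'   (leave-one-subject-out), `"leave_one_trial_out"` (one fold per
#'   subject/session pair) or `"temporal_nonshuffled"` (per subject, first
#'   `train_fraction` of each state stream in temporal order trains; the
#'   first `buffer_discard` test samples are dropped as an autocorrelation
#'   buffer).
#' @param train_fraction training fraction for the random and temporal
#'   splits (0.8 and 0.85 respectively by default conventions).
#' @param buffer_discard test samples discarded after the temporal split
#'   point (default 17).
#' @param seed RNG seed for the random splits.
#' @return List of class `"protocol_spec"`.
#' @export
protocol_spec <- function(kind = c("intra_subject", "pooled_inter_subject",
                                   "loso", "leave_one_trial_out",
                                   "temporal_nonshuffled"),
                          train_fraction = NULL, buffer_discard = 17L,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(train_fraction))
    train_fraction <- if (kind == "temporal_nonshuffled") 0.85 else 0.8
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (buffer_discard < 0) stop("buffer_discard must be >= 0")
  structure(list(kind = kind, train_fraction = train_fraction,
                 buffer_discard = as.integer(buffer_discard),
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Train/test folds under a validation protocol
#'
#' `meta` carries each sample's provenance: `subject`, `session`,
#' `t_start` and `label`. Folds are lists of disjoint `train` / `test`
#' index vectors into the rows of `meta`.
#'
#' @param meta data.frame with columns `subject`, `session`, `t_start`,
#'   `label` (one row per sample).
#' @param spec a [protocol_spec()].
#' @return List of folds, each `list(train =, test =, id =)`.
#' @export
split_protocol <- function(meta, spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  meta <- as.data.frame(meta)
  need <- switch(spec$kind,
                 intra_subject = c("subject"),
                 pooled_inter_subject = character(0),
                 loso = c("subject"),
                 leave_one_trial_out = c("subject", "session"),
                 temporal_nonshuffled = c("subject", "label", "t_start"))
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("protocol '", spec$kind, "' needs provenance column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(meta)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  random_split <- function(idx, frac) {
    idx <- sample(idx)
    n_tr <- floor(frac * length(idx))
    list(train = sort(idx[seq_len(n_tr)]), test = sort(idx[-seq_len(n_tr)]))
  }
  if (spec$kind == "pooled_inter_subject") {
    f <- random_split(seq_len(n), spec$train_fraction)
    return(list(c(f, id = "pooled")))
  }
  if (spec$kind == "intra_subject") {
    return(lapply(unique(meta$subject), function(s) {
      f <- random_split(which(meta$subject == s), spec$train_fraction)
      c(f, id = as.character(s))
    }))
  }
  if (spec$kind == "loso") {
    return(lapply(unique(meta$subject), function(s) {
      list(train = which(meta$subject != s),
           test = which(meta$subject == s), id = as.character(s))
    }))
  }
  if (spec$kind == "leave_one_trial_out") {
    trial <- paste(meta$subject, meta$session, sep = "/")
    return(lapply(unique(trial), function(tr) {
      list(train = which(trial != tr), test = which(trial == tr), id = tr)
    }))
  }
  # temporal_nonshuffled: per subject, split each state stream in temporal
  # order, then drop the first buffer_discard test samples of each stream.
  lapply(unique(meta$subject), function(s) {
    tr_idx <- integer(0); te_idx <- integer(0)
    for (lb in unique(meta$label[meta$subject == s])) {
      idx <- which(meta$subject == s & meta$label == lb)
      idx <- idx[order(meta$t_start[idx])]
      n_tr <- floor(spec$train_fraction * length(idx))
      tr_idx <- c(tr_idx, idx[seq_len(n_tr)])
      te <- idx[-seq_len(n_tr)]
      if (length(te) > spec$buffer_discard)
        te_idx <- c(te_idx, te[-seq_len(spec$buffer_discard)])
    }
    list(train = sort(tr_idx), test = sort(te_idx), id = as.character(s))
  })
}

#' Train an RBF-kernel SVM with grid-searched hyperparameters
#'
#' Five-fold stratified cross-validation over a `C x gamma` grid; the grid
#' point with the best mean CV accuracy is chosen (ties resolved towards
#' smaller `C`, then smaller `gamma`) and the final model is refitted on
#' all training rows. `gamma = "scale"` resolves to
#' `1 / (p * var(x))` (overall matrix variance).
#'
#' @param x training matrix.
#' @param y training labels.
#' @param cost_grid candidate `C` values.
#' @param gamma_grid candidate `gamma` values (may include `"scale"`).
#' @param cv_folds folds (default 5); every class needs >= `cv_folds`
#'   training samples.
#' @param seed RNG seed for fold assignment.
#' @return List of class `"svm_fit"` with `model`, `cost`, `gamma`,
#'   `cv_accuracy`.
#' @export
svm_train <- function(x, y, cost_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(1e-3, 1e-2, 1e-1, 1, "scale"),
                      cv_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  tab <- table(y)
  if (any(tab < cv_folds))
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " samples (< ", cv_folds, " folds); stratification impossible -- ",
         "reduce cv_folds or rebalance the training set")
  vx <- stats::var(as.vector(x))
  gam <- vapply(gamma_grid, function(g)
    if (identical(g, "scale")) 1 / (ncol(x) * max(vx, 1e-12))
    else as.numeric(g), 0)
  grid <- expand.grid(cost = as.numeric(cost_grid), gamma = gam)
  grid <- grid[order(grid$cost, grid$gamma), ]
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[gi], gamma = grid$gamma[gi],
                      scale = FALSE)
      hits <- hits + sum(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / length(y)
  }, 0)
  best <- which.max(acc)          # grid pre-sorted: ties -> smaller C, gamma
  model <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = FALSE)
  structure(list(model = model, cost = grid$cost[best],
                 gamma = grid$gamma[best], cv_accuracy = acc[best]),
            class = "svm_fit")
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  as.character(stats::predict(object$model, as.matrix(newdata)))
}

#' Classification metrics (percent)
#'
#' Accuracy plus macro-averaged F1, recall and precision, as percentages,
#' with the per-class F1 defined as 0 when precision + recall is 0.
#'
#' @param y_true,y_pred label vectors of equal positive length.
#' @return List with `accuracy`, `f1`, `recall`, `precision` (percent),
#'   `per_class` (data.frame) and `confusion` (matrix, true x predicted).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vector lengths differ")
  if (length(y_true) == 0L) stop("cannot score empty label vectors")
  lv <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = lv)
  yp <- factor(as.character(y_pred), levels = lv)
  cm <- table(true = yt, predicted = yp)
  per <- lapply(lv, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  rownames(per) <- lv
  list(accuracy = 100 * sum(diag(cm)) / length(yt),
       f1 = 100 * mean(per[, "f1"]),
       recall = 100 * mean(per[, "recall"]),
       precision = 100 * mean(per[, "precision"]),
       per_class = as.data.frame(per), confusion = unclass(cm))
}

#' Granger-causality indegree
#'
#' Total incoming causal flow per channel. Under the storage convention
#' `m[a, b] = GC(b -> a)`, the indegree of channel `i` is the off-diagonal
#' row sum `sum_j m[i, j]`.
#'
#' @param gc a square GC matrix (convention `[target, source]`).
#' @param metric declared metric of the matrix; must be `"GC"`.
#' @return Numeric vector of per-channel indegrees.
#' @export
gc_indegree <- function(gc, metric = "GC") {
  if (!identical(metric, "GC"))
    stop("indegree is defined for GC matrices, got metric '", metric, "'")
  gc <- as.matrix(gc)
  rowSums(gc) - diag(gc)
}

#' One-way ANOVA across state groups
#'
#' Classic one-way F test (equal-variance) on >= 2 groups of >= 2 values
#' each; unequal group sizes supported.
#'
#' @param groups list of numeric vectors (one per state).
#' @return List with `F` and `p`.
#' @export
state_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}
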