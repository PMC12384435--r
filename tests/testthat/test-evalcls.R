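test_that("SVM training selects hyperparameters deterministically", {
  set.seed(33)
  y <- rep(0:2, each = 20)
  X <- matrix(rnorm(60 * 2, sd = 0.2), 60) + cbind(y == 1, y == 2) * 3
  f1 <- svm_train(X, y, seed = 7)
  f2 <- svm_train(X, y, seed = 7)
  expect_equal(f1$cost, f2$cost)
  expect_equal(f1$gamma, f2$gamma)
  expect_equal(mean(predict(f1, X) == as.character(y)), 1)
  expect_gt(f1$cv_accuracy, 0.95)
  small <- c(1:6, 21:26, 41)                     # class 2 has one sample
  expect_error(svm_train(X[small, ], y[small]), "stratification")
})

test_that("the RBF kernel beats a linear baseline on an XOR problem", {
  set.seed(34)
  n <- 200
  X <- matrix(runif(n * 2, -1, 1), n)
  y <- as.integer(xor(X[, 1] > 0, X[, 2] > 0))
  fit <- svm_train(X, y, cv_folds = 5, seed = 1)
  lin_acc <- mean(vapply(1:5, function(f) {
    te <- seq(f, n, by = 5)
    m <- e1071::svm(X[-te, ], factor(y[-te]), kernel = "linear",
                    scale = FALSE)
    mean(predict(m, X[te, ]) == factor(y[te], levels = levels(factor(y))))
  }, 0))
  expect_gt(fit$cv_accuracy, lin_acc + 0.2)
})

test_that("protocol splits are disjoint with the declared structure", {
  meta <- data.frame(subject = rep(paste0("S", 1:5), each = 40),
                     session = rep(rep(c("a", "b"), each = 20), 5),
                     t_start = rep(seq(0, 234, by = 6), 5),
                     label = rep(rep(0:2, length.out = 40), 5))
  spec <- protocol_spec("loso")
  folds <- split_protocol(meta, spec)
  expect_length(folds, 5L)
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tested, seq_len(nrow(meta)))      # each row tested once
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_equal(unique(meta$subject[f$test]),
                 setdiff(paste0("S", 1:5), unique(meta$subject[f$train])))
  }
  f_in <- split_protocol(meta[meta$subject == "S1", ],
                         protocol_spec("intra_subject", seed = 2))[[1]]
  expect_length(f_in$train, 32L)
  expect_length(f_in$test, 8L)
  expect_length(intersect(f_in$train, f_in$test), 0L)
  folds_tr <- split_protocol(meta, protocol_spec("leave_one_trial_out"))
  expect_length(folds_tr, 10L)                   # 5 subjects x 2 sessions
  expect_error(split_protocol(meta[, c("t_start", "label")],
                              protocol_spec("loso")), "provenance")
})

test_that("temporal splits respect order and discard the buffer", {
  meta <- data.frame(subject = "S1",
                     session = "a",
                     t_start = rep(seq(0, 1194, by = 6), 3),
                     label = rep(0:2, each = 200))
  spec <- protocol_spec("temporal_nonshuffled")
  fold <- split_protocol(meta, spec)[[1]]
  for (lb in 0:2) {
    tr <- fold$train[meta$label[fold$train] == lb]
    te <- fold$test[meta$label[fold$test] == lb]
    expect_length(tr, 170L)                      # first 85% in time
    expect_length(te, 200L - 170L - 17L)         # buffer of 17 discarded
    expect_lt(max(meta$t_start[tr]), min(meta$t_start[te]))
    # the 17 samples right after the split point appear in neither set
    stream <- which(meta$label == lb)
    buffer <- stream[171:187]
    expect_length(intersect(fold$train, buffer), 0L)
    expect_length(intersect(fold$test, buffer), 0L)
  }
})

test_that("metrics match confusion-matrix arithmetic", {
  m <- compute_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 100)
  # constant prediction on a balanced 3-class set
  mc <- compute_metrics(rep(0:2, each = 4), rep(1, 12))
  expect_equal(mc$accuracy, 100 / 3, tolerance = 1e-10)
  expect_equal(mc$recall, 100 / 3, tolerance = 1e-10)
  expect_equal(mc$f1, 100 / 6, tolerance = 1e-10)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
  expect_error(compute_metrics(1:3, 1:2), "lengths differ")
})

test_that("metrics agree with a brute-force oracle over label vectors", {
  # exhaustive over short vectors, seeded sample of longer ones
  for (len in 1:2) {
    combos <- expand.grid(rep(list(0:2), 2 * len))
    for (r in seq_len(nrow(combos))) {
      yt <- as.integer(combos[r, 1:len])
      yp <- as.integer(combos[r, (len + 1):(2 * len)])
      got <- compute_metrics(yt, yp)
      want <- oracle_metrics(yt, yp)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$f1, want$f1)
      expect_equal(got$recall, want$recall)
      expect_equal(got$precision, want$precision)
    }
  }
  set.seed(44)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    yt <- sample(0:2, n, replace = TRUE)
    yp <- sample(0:2, n, replace = TRUE)
    got <- compute_metrics(yt, yp)
    want <- oracle_metrics(yt, yp)
    expect_equal(got$f1, want$f1)
    expect_equal(got$precision, want$precision)
    expect_equal(sum(got$confusion), n)
  }
})

test_that("GC indegree sums incoming flow under the storage convention", {
  expect_equal(gc_indegree(matrix(0, 4, 4)), rep(0, 4))
  m <- matrix(0, 3, 3)
  m[1, 3] <- 0.7                                 # GC(3 -> 1)
  expect_equal(gc_indegree(m), c(0.7, 0, 0))
  expect_error(gc_indegree(m, metric = "PLV"), "GC")
})

test_that("seeded coupling raises the target's indegree, not the source's", {
  set.seed(55)
  n <- 4000
  src <- rnorm(n)
  tgt <- 0.7 * c(0, src[-n]) + rnorm(n, sd = 0.6)
  other <- rnorm(n)
  X <- rbind(tgt, src, other)
  G <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    if (a != b) G[a, b] <- granger_pairwise(X[a, ], X[b, ], p = 3)
  ind <- gc_indegree(G)
  expect_gt(ind[1], ind[2])
  expect_gt(ind[1], ind[3])
})

test_that("one-way ANOVA matches manual sums of squares", {
  expect_equal(state_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  got <- state_anova(list(c(1, 2, 3), c(4, 5, 6)))
  # manual: SSB = 13.5 (df 1), SSW = 4 (df 4) -> F = 13.5
  expect_equal(got$F, 13.5)
  expect_equal(got$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  set.seed(66)
  groups <- list(rnorm(200), rnorm(200), rnorm(200, mean = 1))
  expect_lt(state_anova(groups)$p, 1e-3)
  # unequal sizes against the textbook formula
  g <- list(c(2, 4, 3, 5), c(8, 9, 7), c(1, 2))
  vals <- unlist(g); grand <- mean(vals)
  ssb <- sum(lengths(g) * (vapply(g, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  f_manual <- (ssb / 2) / (ssw / (length(vals) - 3))
  expect_equal(state_anova(g)$F, f_manual)
  expect_error(state_anova(list(1, c(2, 3))), "at least 2 values")
})
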