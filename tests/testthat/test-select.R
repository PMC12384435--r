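test_that("subsets are 3 + 2C disjoint index sets", {
  cfg7 <- pipeline_config("7ch")
  s7 <- make_subsets(feature_layout(cfg7), cfg7)
  expect_length(s7, 17L)
  idx <- unlist(s7)
  expect_equal(length(idx), length(unique(idx)))
  expect_equal(sum(lengths(s7)[1:3]), 315L)      # per-band value blocks
  cfg32 <- pipeline_config("32ch")
  expect_length(make_subsets(feature_layout(cfg32), cfg32), 67L)
  expect_error(make_subsets(feature_layout(cfg7), cfg32), "montage")
})

test_that("subset LDA separates constructed classes in 2 dimensions", {
  set.seed(24)
  n <- 60
  y <- rep(0:2, each = n / 3)
  shift <- cbind(c(0, 4, 0), c(0, 0, 4), c(4, 4, 0), c(2, -2, 0))
  X <- matrix(rnorm(n * 4, sd = 0.3), n) + shift[y + 1, ]
  st <- lda_project_subsets(X, y, list(a = 1:2, b = 3:4))
  expect_equal(dim(st$projected), c(n, 4L))
  for (block in list(1:2, 3:4)) {
    P <- st$projected[, block]
    cents <- rbind(colMeans(P[y == 0, ]), colMeans(P[y == 1, ]),
                   colMeans(P[y == 2, ]))
    within <- mean(vapply(0:2, function(cl)
      mean(sqrt(rowSums(sweep(P[y == cl, ], 2, cents[cl + 1, ])^2))), 0))
    between <- min(dist(cents))
    expect_gt(between, 3 * within)
  }
  expect_error(lda_project_subsets(X[y != 2, ], y[y != 2],
                                   list(a = 1:2)), "classes")
})

test_that("subset LDA agrees with MASS::lda directions on clean data", {
  skip_if_not_installed("MASS")
  set.seed(25)
  y <- rep(0:2, each = 30)
  X <- matrix(rnorm(90 * 3), 90) + cbind(y == 1, y == 2, y == 0) * 3
  st <- lda_project_subsets(X, y, list(all = 1:3), ridge = 1e-10)
  ref <- MASS::lda(X, grouping = y)
  # compare one-dimensional subspaces via absolute cosine similarity
  v1 <- st$bases$all$V[, 1]; w1 <- ref$scaling[, 1]
  expect_gt(abs(sum(v1 * w1)) / sqrt(sum(v1^2) * sum(w1^2)), 0.99)
})

test_that("z-scoring standardizes training rows and reuses train stats", {
  set.seed(26)
  X <- matrix(rnorm(40), 10)
  X[, 4] <- 7                                    # constant column
  sc <- zscore_fit(X)
  Z <- zscore_apply(sc, X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(apply(Z[, 1:3], 2, sd), rep(1, 3))
  expect_true(all(Z[, 4] == 0))
  # hand-checked 2x2: train mean 1, sd sqrt(2)
  sc2 <- zscore_fit(matrix(c(0, 2, 0, 2), 2))
  expect_equal(zscore_apply(sc2, matrix(c(3, 3), 1))[1, 1],
               (3 - 1) / sqrt(2))
  expect_error(zscore_fit(X[1, , drop = FALSE]), "2 rows")
})

test_that("correlation pruning drops later near-duplicates only", {
  set.seed(27)
  x1 <- rnorm(50)
  x2 <- x1 + rnorm(50, sd = 0.05)          # |r| > 0.9 with x1
  x3 <- rnorm(50)                          # independent
  stopifnot(abs(cor(x1, x2)) > 0.9, abs(cor(x1, x3)) < 0.9)
  kept <- correlation_prune(cbind(x1, x2, x3))
  expect_equal(kept, c(1L, 3L))
  expect_equal(correlation_prune(cbind(x1, x1)), 1L)
  orth <- qr.Q(qr(matrix(rnorm(100), 20)))
  expect_equal(correlation_prune(orth), 1:5)
  # no kept pair exceeds the threshold (greedy-rule postcondition)
  X <- matrix(rnorm(50 * 12), 50)
  X[, 7] <- X[, 2] * 1.01 + rnorm(50, sd = 0.01)
  kept2 <- correlation_prune(X)
  R <- abs(cor(X[, kept2]))
  expect_true(all(R[upper.tri(R)] <= 0.9 + 1e-12))
})

test_that("random-forest ranking finds the informative feature", {
  set.seed(28)
  y <- rep(0:2, each = 30)
  hits <- 0L
  for (s in 1:100) {
    X <- cbind(y + rnorm(90, sd = 0.1), matrix(rnorm(90 * 50), 90))
    rk <- rf_rank_select(X, y, top_k = 5L, seed = s)
    if (rk$top[1] == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  X <- matrix(rnorm(90 * 60), 90)
  r1 <- rf_rank_select(X, y, seed = 34L)
  r2 <- rf_rank_select(X, y, seed = 34L)
  expect_identical(r1$top, r2$top)
  expect_length(r1$top, 45L)
  expect_error(rf_rank_select(X[, 1:10], y, top_k = 45L), "exceeds")
})

test_that("the fitted selection pipeline reaches 45 features from 305", {
  fx <- fixture_features_7ch()
  cfg <- pipeline_config("7ch")
  sel <- fit_selection(fx$x, fx$meta$label, fx$layout, cfg)
  expect_equal(stage2_ncol(sel), 305L)
  expect_length(sel$top, 45L)
  out <- apply_selection(sel, fx$x)
  expect_equal(dim(out), c(nrow(fx$x), 45L))
  # PLI-derived graph descriptors are excluded from stage 2
  pli_idx <- layout_indices(fx$layout, "^graph_.*_PLI$")
  expect_length(pli_idx, 30L)
  expect_length(intersect(sel$stage2_idx, pli_idx), 0L)
  # stage-2 passthrough is stats + non-PLI graph + zero-crossing
  expect_length(sel$stage2_idx, 150L + 120L + 1L)
})

test_that("selection state is a function of training rows only", {
  fx <- fixture_features_7ch()
  cfg <- pipeline_config("7ch")
  train <- seq_len(18)
  sel <- fit_selection(fx$x[train, ], fx$meta$label[train], fx$layout, cfg)
  # test rows are standardized with the training scaler: training columns
  # are centred, held-out projections generally are not
  z_train <- apply_selection(sel, fx$x[train, ])
  z_test <- apply_selection(sel, fx$x[-train, , drop = FALSE])
  expect_equal(nrow(z_test), nrow(fx$x) - 18L)
  # refitting on the same training rows reproduces the model exactly
  sel2 <- fit_selection(fx$x[train, ], fx$meta$label[train], fx$layout, cfg)
  expect_identical(sel$top, sel2$top)
  expect_identical(sel$kept, sel2$kept)
  expect_identical(z_train, apply_selection(sel2, fx$x[train, ]))
})
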