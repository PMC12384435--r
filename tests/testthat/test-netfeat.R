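test_that("binarization is strict, symmetric and bounded", {
  W <- matrix(c(0, .3, .7, .3, 0, .5, .7, .5, 0), 3)
  expect_equal(sum(binarize_at(W, 0)), 6)        # complete
  expect_equal(sum(binarize_at(W, 1)), 0)        # empty
  expect_equal(binarize_at(W, 0.5)[2, 3], 0)     # strict > at the boundary
  expect_equal(binarize_at(W, 0.49)[2, 3], 1)
  expect_error(binarize_at(W, 1.5), "\\[0, 1\\]")
  # directed input symmetrized by max
  Wd <- matrix(0, 3, 3); Wd[1, 2] <- 0.9
  A <- binarize_at(Wd, 0.5)
  expect_equal(A[2, 1], 1)
})

test_that("graph metrics match closed forms on canonical graphs", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  m <- graph_metrics(K5)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$mean_clustering, 1)
  expect_equal(m$mean_degree, 4)
  empty <- matrix(0, 4, 4)
  me <- graph_metrics(empty)
  expect_equal(unlist(me), c(global_efficiency = 0, local_efficiency = 0,
                             mean_clustering = 0, mean_degree = 0))
  P3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  expect_equal(graph_metrics(P3)$global_efficiency, 5 / 6)
  expect_error(graph_metrics(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(graph_metrics(matrix(0, 2, 3)), "square")
})

test_that("graph metrics agree with brute-force BFS on small graphs", {
  # exhaustive up to 5 nodes, seeded sample of 6-node graphs
  check <- function(A) {
    got <- graph_metrics(A)
    want <- oracle_graph_metrics(A)
    expect_equal(got$global_efficiency, want$global_efficiency)
    expect_equal(got$local_efficiency, want$local_efficiency)
    expect_equal(got$mean_clustering, want$mean_clustering)
    expect_equal(got$mean_degree, want$mean_degree)
  }
  for (n in 3:5) {
    ne <- n * (n - 1) / 2
    for (code in 0:(2^ne - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(ne)]
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- bits
      A <- A + t(A)
      check(A)
    }
  }
  set.seed(77)
  for (i in 1:150) {
    A <- matrix(0, 6, 6)
    A[upper.tri(A)] <- rbinom(15, 1, runif(1, 0.2, 0.8))
    A <- A + t(A)
    check(A)
  }
})

test_that("graph metrics cross-check against igraph on random graphs", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    D <- igraph::distances(g)
    inv <- 1 / D; diag(inv) <- 0
    ge_ig <- sum(inv[is.finite(inv)]) / (n * (n - 1))
    cc_ig <- igraph::transitivity(g, type = "local", isolates = "zero")
    m <- graph_metrics(A)
    expect_equal(m$global_efficiency, ge_ig)
    expect_equal(m$mean_clustering, mean(cc_ig))
    expect_equal(m$mean_degree, mean(igraph::degree(g)))
  }
})

test_that("threshold profiles have the configured descriptor lengths", {
  cfg7 <- pipeline_config("7ch")
  cfg32 <- pipeline_config("32ch")
  set.seed(5)
  W <- matrix(runif(49), 7); diag(W) <- 0
  d7 <- threshold_profile(W, cfg7$n_thresholds, cfg7$graph_menu,
                          cfg7$graph_connected_count)
  expect_length(d7, 10L)
  expect_equal(graph_descriptor_length(cfg7), 10L)
  W32 <- matrix(runif(32 * 32), 32); diag(W32) <- 0
  d32 <- threshold_profile(W32, cfg32$n_thresholds, cfg32$graph_menu,
                           cfg32$graph_connected_count)
  expect_length(d32, 35L)
  expect_equal(graph_descriptor_length(cfg32), 35L)
  expect_true(all(is.finite(d32)))
  # all-zero matrix: every descriptor in the core menu is 0
  expect_true(all(threshold_profile(matrix(0, 7, 7), 130L,
                                    cfg7$graph_menu, FALSE) == 0))
  expect_error(threshold_profile(W * 3, 130L, cfg7$graph_menu, FALSE),
               "\\[0, 1\\]")
})

test_that("mean descriptors times threshold count equal sum descriptors", {
  set.seed(6)
  W <- matrix(runif(49), 7); diag(W) <- 0
  d <- threshold_profile(W, 130L, pipeline_config("7ch")$graph_menu, FALSE)
  sums <- d[grep("_sum$", names(d))]
  means <- d[grep("_mean$", names(d))]
  expect_equal(unname(sums), unname(means) * 130)
})

test_that("edge count decreases monotonically with the threshold", {
  set.seed(7)
  W <- matrix(runif(64), 8); diag(W) <- 0
  counts <- vapply(seq(0, 1, length.out = 130),
                   function(t) sum(binarize_at(W, t)) / 2, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("upper-triangle extraction is row-major with forced lengths", {
  W <- matrix(1:9, 3, byrow = TRUE)
  expect_equal(upper_triangle(W), c(2, 3, 6))     # (1,2), (1,3), (2,3)
  expect_length(upper_triangle(matrix(0, 7, 7)), 21L)
  expect_length(upper_triangle(matrix(0, 32, 32)), 496L)
  expect_length(upper_triangle(matrix(0, 2, 2)), 1L)
  # 15 matrices x per-matrix lengths give the printed local-feature totals
  expect_equal(15L * 21L, 315L)
  expect_equal(15L * 496L, 7440L)
})

test_that("unit rescaling maps GC matrices into the threshold domain", {
  set.seed(8)
  G <- matrix(rexp(49, 0.5), 7); diag(G) <- 0
  R <- rescale_unit(G)
  off <- R[row(R) != col(R)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  expect_true(all(rescale_unit(matrix(2, 4, 4)) == 0))
})
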