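#' Binarize a weighted connectivity matrix at a threshold
#'
#' Directed matrices are symmetrized by the elementwise maximum first; an
#' undirected edge `(i, j)` is present iff `max(W_ij, W_ji) > t` (strict
#' inequality). The diagonal is always 0.
#'
#' @param W square numeric matrix with weights in `[0, 1]`.
#' @param t threshold in `[0, 1]`.
#' @return 0/1 symmetric adjacency matrix.
#' @export
binarize_at <- function(W, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
    stop("threshold must be a single value in [0, 1]")
  S <- pmax(W, t(W))
  A <- (S > t) * 1
  diag(A) <- 0
  A
}

# BFS shortest-path distances of a 0/1 adjacency matrix via boolean matrix
# powers; Inf where unreachable, 0 on the diagonal.
.adj_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  if (n <= 2L) return(D)
  walk <- A
  for (s in 2L:(n - 1L)) {
    walk <- (walk %*% A > 0) * 1
    new <- walk == 1 & is.infinite(D)
    if (!any(new)) break
    D[new] <- s
  }
  D
}

.global_efficiency_D <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1L))
}

#' Graph-theoretic metrics of a binary adjacency matrix
#'
#' Global efficiency (mean inverse shortest-path length over ordered pairs,
#' `1/Inf = 0`), local efficiency (mean over nodes of the global efficiency
#' of each neighbourhood subgraph), mean Watts-Strogatz clustering
#' coefficient (0 for degree < 2) and mean node degree.
#'
#' @param A square symmetric 0/1 matrix with zero diagonal.
#' @return Named list with `global_efficiency`, `local_efficiency`,
#'   `mean_clustering`, `mean_degree`.
#' @export
graph_metrics <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (any(abs(A - t(A)) > 1e-12)) stop("adjacency matrix must be symmetric")
  deg <- colSums(A)
  n <- nrow(A)
  D <- .adj_distances(A)
  ge <- .global_efficiency_D(D)
  le <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    .global_efficiency_D(.adj_distances(A[nb, nb, drop = FALSE]))
  }, 0))
  A2 <- A %*% A
  tri <- diag(A2 %*% A) / 2          # triangles through each node
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  list(global_efficiency = ge, local_efficiency = le,
       mean_clustering = mean(cc), mean_degree = mean(deg))
}

# Connected components from a distance matrix (finite = reachable).
.components_D <- function(D) {
  n <- nrow(D)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[is.finite(D[i, ])] <- cid
    }
  }
  comp
}

# Full scalar menu for one adjacency matrix. Items beyond the core four are
# used by the extended (32-channel) descriptor menu.
.graph_menu_values <- function(A, menu) {
  n <- nrow(A)
  deg <- colSums(A)
  D <- .adj_distances(A)
  base <- graph_metrics(A)
  comp <- .components_D(D)
  sizes <- tabulate(comp)
  big <- which.max(sizes)
  vals <- list(
    global_efficiency = base$global_efficiency,
    local_efficiency = base$local_efficiency,
    mean_clustering = base$mean_clustering,
    mean_degree = base$mean_degree,
    max_degree = max(deg)
  )
  need <- function(nm) nm %in% menu
  if (need("degree_variance"))
    vals$degree_variance <- if (n > 1L) stats::var(deg) else 0
  if (need("edge_density"))
    vals$edge_density <- if (n > 1L) sum(A) / (n * (n - 1)) else 0
  if (need("transitivity")) {
    A2 <- A %*% A
    paths2 <- sum(A2) - sum(diag(A2))
    vals$transitivity <- if (paths2 > 0) sum(diag(A2 %*% A)) / paths2 else 0
  }
  if (need("n_components")) vals$n_components <- max(comp)
  if (need("largest_component_fraction"))
    vals$largest_component_fraction <- max(sizes) / n
  if (need("assortativity")) {
    ei <- which(A == 1, arr.ind = TRUE)       # ordered edges, both directions
    vals$assortativity <- if (nrow(ei) < 2L) 0 else {
      r <- suppressWarnings(stats::cor(deg[ei[, 1]], deg[ei[, 2]]))
      if (is.finite(r)) r else 0
    }
  }
  if (need("mean_betweenness") || need("max_betweenness")) {
    bw <- if (sum(A) == 0) numeric(n) else
      igraph::betweenness(igraph::graph_from_adjacency_matrix(
        A, mode = "undirected"), directed = FALSE)
    vals$mean_betweenness <- mean(bw)
    vals$max_betweenness <- max(bw)
  }
  if (need("mean_closeness")) {
    cl <- vapply(seq_len(n), function(i) {
      d <- D[i, -i]
      d <- d[is.finite(d)]
      if (!length(d)) 0 else length(d) / sum(d)
    }, 0)
    vals$mean_closeness <- mean(cl)
  }
  if (need("diameter_largest") || need("mean_eccentricity_largest")) {
    nodes <- which(comp == big)
    if (length(nodes) < 2L) {
      vals$diameter_largest <- 0
      vals$mean_eccentricity_largest <- 0
    } else {
      Dl <- D[nodes, nodes, drop = FALSE]
      ecc <- apply(Dl, 1L, max)
      vals$diameter_largest <- max(ecc)
      vals$mean_eccentricity_largest <- mean(ecc)
    }
  }
  if (need("isolated_count")) vals$isolated_count <- sum(deg == 0)
  unlist(vals[menu])
}

#' Threshold profile of a weighted connectivity matrix
#'
#' Binarizes the matrix at `n_thresholds` linearly spaced thresholds in
#' `[0, 1]`, computes the configured scalar graph metrics at each threshold
#' and aggregates each metric as its sum and mean across thresholds
#' (descriptor order: `<metric>_sum`, `<metric>_mean` in menu order,
#' followed by the connected-threshold count when enabled). Weights must
#' already lie in `[0, 1]`; unbounded metrics (GC) are min-max rescaled per
#' matrix first (see [rescale_unit()]).
#'
#' @param W square weighted matrix with values in `[0, 1]`.
#' @param n_thresholds number of thresholds (default 130).
#' @param menu character vector of scalar metric names.
#' @param connected_count append the number of thresholds yielding a
#'   connected graph?
#' @return Named numeric descriptor vector (length `2 * length(menu)`
#'   plus 1 when `connected_count`).
#' @export
threshold_profile <- function(W, n_thresholds = 130L,
                              menu = .menu_7ch, connected_count = FALSE) {
  if (any(W < -1e-9) || any(W > 1 + 1e-9))
    stop("weights must lie in [0, 1]; rescale unbounded metrics first")
  W <- pmin(pmax(W, 0), 1)
  thr <- seq(0, 1, length.out = n_thresholds)
  Sym <- pmax(W, t(W))
  diag(Sym) <- 0
  wvec <- Sym[upper.tri(Sym)]
  menu_c <- if (connected_count) unique(c(menu, "n_components")) else menu
  cache <- new.env(parent = emptyenv())
  tab <- matrix(0, n_thresholds, length(menu_c),
                dimnames = list(NULL, menu_c))
  for (ti in seq_along(thr)) {
    key <- as.character(sum(wvec > thr[ti]))   # edge set is fixed by count
    if (is.null(cache[[key]])) {
      A <- binarize_at(W, thr[ti])
      cache[[key]] <- .graph_menu_values(A, menu_c)
    }
    tab[ti, ] <- cache[[key]]
  }
  desc <- as.vector(rbind(colSums(tab[, menu, drop = FALSE]),
                          colMeans(tab[, menu, drop = FALSE])))
  names(desc) <- as.vector(rbind(paste0(menu, "_sum"), paste0(menu, "_mean")))
  if (connected_count) {
    nc <- sum(tab[, "n_components"] == 1)
    desc <- c(desc, connected_thresholds = nc)
  }
  desc
}

#' Min-max rescale a matrix to the unit interval
#'
#' Off-diagonal values are mapped linearly onto `[0, 1]`; a constant matrix
#' maps to all zeros. Used for unbounded metrics (GC) before thresholding.
#'
#' @param W square numeric matrix.
#' @return Rescaled matrix with zero diagonal.
#' @export
rescale_unit <- function(W) {
  off <- W[row(W) != col(W)]
  lo <- min(off); hi <- max(off)
  out <- if (hi - lo < 1e-15) W * 0 else (W - lo) / (hi - lo)
  diag(out) <- 0
  pmin(pmax(out, 0), 1)
}

#' Strict upper-triangular values of a matrix
#'
#' Row-major strict upper triangle of the weighted (unthresholded) matrix:
#' `M (M - 1) / 2` values.
#'
#' @param W square matrix.
#' @return Numeric vector of length `M (M - 1) / 2`.
#' @export
upper_triangle <- function(W) {
  if (nrow(W) != ncol(W)) stop("matrix must be square")
  t(W)[lower.tri(t(W))]    # row-major order of the upper triangle
}
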