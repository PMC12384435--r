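#' Instantaneous phase of a band-limited signal
#'
#' Analytic-signal (Hilbert-transform) phase, the standard choice for
#' phase-synchrony metrics on band-filtered data.
#'
#' @param x numeric vector, non-constant.
#' @return Phase series in radians, values in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 2L || stats::sd(x) < 1e-15)
    stop("instantaneous phase is undefined for a constant signal")
  phi <- Arg(.analytic_signal(x))
  phi[phi <= -pi] <- pi
  phi
}

# FFT analytic signal: zero the negative frequencies, double the positive.
.analytic_signal <- function(x) {
  N <- length(x)
  h <- numeric(N)
  if (N %% 2L == 0L) {
    h[c(1L, N / 2L + 1L)] <- 1
    h[2:(N / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((N + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / N
}

#' Phase locking value
#'
#' `|mean(exp(i (phi_x - phi_y)))|`: 1 for perfectly locked phases, 0 for
#' uniformly scattered phase differences.
#'
#' @param phix,phiy phase series of equal length (radians).
#' @return Value in `[0, 1]`.
#' @export
plv <- function(phix, phiy) {
  if (length(phix) != length(phiy)) stop("phase series lengths differ")
  Mod(mean(exp(1i * (phix - phiy))))
}

#' Phase lag index
#'
#' `|mean(sign(wrapped(phi_x - phi_y)))|` with the sign of the wrapped
#' difference taken as `sign(sin(phi_x - phi_y))`, so zero-lag and antiphase
#' differences contribute 0. Robust to volume-conduction (zero-lag)
#' coupling.
#'
#' @param phix,phiy phase series of equal length (radians).
#' @return Value in `[0, 1]`.
#' @export
pli <- function(phix, phiy) {
  if (length(phix) != length(phiy)) stop("phase series lengths differ")
  s <- sin(phix - phiy)
  s[abs(s) < 1e-12] <- 0              # exact 0 / pi differences count as 0
  abs(mean(sign(s)))
}

# ---- nonlinear interdependence S ---------------------------------------

# Delay embedding: rows are time indices n = (d-1)*tau + 1 .. N, columns the
# lagged coordinates (x(n), x(n - tau), ..., x(n - (d-1) tau)).
.delay_embed <- function(x, d, tau) {
  N <- length(x)
  n0 <- (d - 1L) * tau + 1L
  idx <- n0:N
  E <- matrix(0, length(idx), d)
  for (j in seq_len(d)) E[, j] <- x[idx - (j - 1L) * tau]
  E
}

# Squared-distance rows from reference points to all embedded points, plus
# each reference's k nearest neighbours (Theiler window excluded, ties
# broken by lower time index).
.embed_neighbors <- function(E, k, refs, theiler) {
  Np <- nrow(E)
  D <- matrix(0, length(refs), Np)
  for (j in seq_len(ncol(E)))
    D <- D + outer(E[refs, j], E[, j], "-")^2
  Dx <- D
  for (r in seq_along(refs)) {
    excl <- max(1L, refs[r] - theiler):min(Np, refs[r] + theiler)
    Dx[r, excl] <- Inf
  }
  # k successive vectorized argmin passes; ties resolve to the lower index
  nn <- matrix(0L, length(refs), k)
  for (j in seq_len(k)) {
    nn[, j] <- max.col(-Dx, ties.method = "first")
    Dx[cbind(seq_len(nrow(Dx)), nn[, j])] <- Inf
  }
  list(D = D, nn = nn)
}

#' Nonlinear interdependence S index
#'
#' Delay-embeds both series; for each embedded reference point of `x`,
#' compares the mean squared distance to its own k nearest neighbours with
#' the mean squared distance to the points selected by `y`'s neighbour time
#' indices, and returns the mean ratio. `S(X|X) = 1`; `S <= 1` always
#' (a point's own nearest neighbours minimize the distance); values near 1
#' indicate strong synchronization. Self-matches are excluded with a
#' Theiler window of `tau * (d - 1)` samples.
#'
#' @param x,y numeric series of equal length.
#' @param d embedding dimension (default 3).
#' @param tau embedding delay in samples (default 1).
#' @param k neighbour count (default 4).
#' @param max_ref maximum number of reference points; when the embedded
#'   series is longer, evenly spaced references are used (neighbours are
#'   still searched over all points). `Inf` uses every point.
#' @return Value in `(0, 1]`.
#' @export
s_index <- function(x, y, d = 3L, tau = 1L, k = 4L, max_ref = Inf) {
  if (length(x) != length(y)) stop("series lengths differ")
  Np <- length(x) - (d - 1L) * tau
  if (Np <= k + 1L)
    stop("series too short: N - (d-1)*tau must exceed k + 1")
  theiler <- tau * (d - 1L)
  if (Np - (2L * theiler + 1L) < k)
    stop("series too short for k neighbours outside the Theiler window")
  refs <- if (Np <= max_ref) seq_len(Np) else
    unique(as.integer(round(seq(1L, Np, length.out = max_ref))))
  Ex <- .delay_embed(x, d, tau)
  Ey <- .delay_embed(y, d, tau)
  hx <- .embed_neighbors(Ex, k, refs, theiler)
  hy <- .embed_neighbors(Ey, k, refs, theiler)
  .s_from_parts(hx$D, hx$nn, hy$nn)
}

.s_from_parts <- function(Dx, nn_own, nn_cond) {
  nref <- nrow(Dx)
  k <- ncol(nn_own)
  ri <- rep(seq_len(nref), k)
  r_own <- rowMeans(matrix(Dx[cbind(ri, as.vector(nn_own))], nref))
  r_cond <- rowMeans(matrix(Dx[cbind(ri, as.vector(nn_cond))], nref))
  mean(ifelse(r_cond <= 0, ifelse(r_own <= 0, 1, 0), r_own / r_cond))
}

# ---- MAR / Granger / PDC -----------------------------------------------

#' Fit a multivariate autoregressive (MAR/VAR) model
#'
#' Ordinary least squares over samples `p+1 .. N`, each channel regressed on
#' the `p` lags of all channels. Stores the coefficient matrices, the
#' maximum-likelihood residual covariance, the effective sample count and
#' the companion-matrix spectral radius.
#'
#' @param X numeric matrix, channels x samples.
#' @param p model order (>= 1).
#' @return Object of class `"mar_model"` with fields `p`, `A` (list of
#'   `p` M x M coefficient matrices), `sigma`, `n_effective`,
#'   `spectral_radius`.
#' @export
fit_mar <- function(X, p = 5L) {
  X <- as.matrix(X)
  M <- nrow(X); N <- ncol(X)
  p <- as.integer(p)
  if (p < 1L) stop("order p must be >= 1")
  if (N <= M * p + 1L)
    stop("too few samples (", N, ") for M*p + 1 = ", M * p + 1L)
  Y <- t(X[, (p + 1L):N, drop = FALSE])
  Z <- matrix(0, N - p, M * p)
  for (r in seq_len(p))
    Z[, ((r - 1L) * M + 1L):(r * M)] <- t(X[, (p + 1L - r):(N - r),
                                            drop = FALSE])
  # narrow-band multichannel data is ill-conditioned but not collinear;
  # only flag genuine rank deficiency (duplicated/constant channels)
  qz <- qr(Z, tol = 1e-12)
  if (qz$rank < ncol(Z)) {
    bad <- qz$pivot[qz$rank + 1L]
    ch <- (bad - 1L) %% M + 1L
    stop("rank-deficient regressor matrix (channel ", ch,
         " lag block is collinear)")
  }
  B <- qr.coef(qz, Y)                       # (M*p) x M
  resid <- Y - Z %*% B
  A <- lapply(seq_len(p), function(r)
    t(B[((r - 1L) * M + 1L):(r * M), , drop = FALSE]))
  sigma <- crossprod(resid) / nrow(resid)
  structure(list(p = p, A = A, sigma = (sigma + t(sigma)) / 2,
                 n_effective = N - p, M = M,
                 spectral_radius = .companion_radius(A)),
            class = "mar_model")
}

#' @export
print.mar_model <- function(x, ...) {
  cat("MAR model: ", x$M, " channels, order ", x$p, ", n_eff = ",
      x$n_effective, ", companion spectral radius ",
      signif(x$spectral_radius, 4), "\n", sep = "")
  invisible(x)
}

.ols_resvar <- function(y, Z) {
  B <- qr.coef(qr(Z), y)
  B[is.na(B)] <- 0
  mean((y - Z %*% B)^2)
}

.lag_block <- function(x, p, N) {
  Z <- matrix(0, N - p, p)
  for (r in seq_len(p)) Z[, r] <- x[(p + 1L - r):(N - r)]
  Z
}

#' Pairwise Granger causality
#'
#' `GC(b -> a) = ln(Var(eps_restricted)/Var(eps_full))`, where the
#' restricted model regresses `xa` on its own `p` lags and the full
#' (bivariate) model adds the `p` lags of `xb`; both are fitted over the
#' identical sample range `p+1 .. N`, so nesting guarantees a non-negative
#' value up to numerical noise (clipped at 0). The full-model residual
#' variance is floored at `1e-12` times the restricted variance, keeping
#' the value finite in the noiseless limit.
#'
#' @param xa,xb numeric series of equal length (effect and cause).
#' @param p model order (default 5).
#' @return Non-negative scalar, the causality from `xb` to `xa`.
#' @export
granger_pairwise <- function(xa, xb, p = 5L) {
  if (length(xa) != length(xb)) stop("series lengths differ")
  N <- length(xa)
  if (N <= 2L * p + 1L) stop("too few samples for order ", p)
  y <- xa[(p + 1L):N]
  Za <- .lag_block(xa, p, N)
  Zb <- .lag_block(xb, p, N)
  vr <- .ols_resvar(y, cbind(1, Za))
  vf <- .ols_resvar(y, cbind(1, Za, Zb))
  if (vr <= 0) return(0)
  max(0, log(vr / max(vf, vr * 1e-12)))
}

# GC matrix with storage convention m[a, b] = GC(b -> a) (row = target).
.gc_matrix <- function(X, p) {
  M <- nrow(X); N <- ncol(X)
  lags <- lapply(seq_len(M), function(i) .lag_block(X[i, ], p, N))
  ys <- lapply(seq_len(M), function(i) X[i, (p + 1L):N])
  vr <- vapply(seq_len(M), function(i)
    .ols_resvar(ys[[i]], cbind(1, lags[[i]])), 0)
  G <- matrix(0, M, M)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (a == b) next
    vf <- .ols_resvar(ys[[a]], cbind(1, lags[[a]], lags[[b]]))
    G[a, b] <- if (vr[a] <= 0) 0 else
      max(0, log(vr[a] / max(vf, vr[a] * 1e-12)))
  }
  G
}

#' Partial directed coherence from a MAR model
#'
#' For each normalized frequency `f`, forms
#' `Abar(f) = I - sum_r A_r exp(-i 2 pi f r)` and the column-normalized
#' magnitudes `pi_ij(f) = |abar_ij(f)| / sqrt(abar_j^H abar_j)`, the
#' directed coupling from source channel `j` to target channel `i`.
#' Column sums of squares equal 1 at every frequency by construction.
#'
#' @param model a [fit_mar()] model.
#' @param freqs normalized frequencies (cycles/sample) to evaluate.
#' @param average average across frequencies (default TRUE)?
#' @return M x M matrix (`[i, j]` = coupling j -> i) when averaging, else an
#'   M x M x length(freqs) array.
#' @export
pdc_matrix <- function(model, freqs, average = TRUE) {
  stopifnot(inherits(model, "mar_model"))
  M <- model$M
  out <- array(0, c(M, M, length(freqs)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    Abar <- diag(M) + 0i
    for (r in seq_len(model$p))
      Abar <- Abar - model$A[[r]] * exp(-2i * pi * f * r)
    cn2 <- colSums(Mod(Abar)^2)
    if (any(cn2 <= 1e-24))
      stop("singular frequency response at f = ", signif(f, 6))
    out[, , fi] <- Mod(Abar) / rep(sqrt(cn2), each = M)
  }
  if (average) {
    m <- apply(out, c(1, 2), mean)
    dimnames(m) <- NULL
    m
  } else out
}

# ---- per-segment tensor ------------------------------------------------

#' Connectivity tensor of one segment (5 metrics x 3 bands)
#'
#' Computes PLV, PLI, S, GC and PDC on each band-filtered version of a
#' segment. Symmetric metrics (PLV, PLI) are stored symmetric; directed
#' metrics use the convention `m[target, source]`; all diagonals are 0.
#' PDC comes from the full M-channel MAR model averaged over
#' `pdc_n_freqs` frequencies spanning the band; GC is pairwise bivariate;
#' S uses delay embedding with the configured `d`, `tau`, `k`.
#'
#' @param seg_by_band named list of band-filtered segments (names must
#'   cover the configured bands), all with the same channel count.
#' @param config an [pipeline_config()].
#' @return Object of class `"connectivity_tensor"`: list with `matrices`
#'   (named `"<metric>.<band>"`), `metrics`, `bands`, `M`.
#' @export
connectivity_tensor <- function(seg_by_band, config = pipeline_config("7ch")) {
  bands <- names(config$bands)
  miss <- setdiff(bands, names(seg_by_band))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  Ms <- vapply(seg_by_band[bands], function(s) nrow(s$data), 0L)
  if (length(unique(Ms)) != 1L) stop("bands disagree on channel count")
  M <- Ms[[1L]]
  sp <- config$s_index
  mats <- list()
  for (b in bands) {
    X <- seg_by_band[[b]]$data
    fs <- seg_by_band[[b]]$fs
    N <- ncol(X)
    # phases
    Phi <- t(apply(X, 1L, instantaneous_phase))
    E <- exp(1i * Phi)
    Cmat <- (E %*% Conj(t(E))) / N
    P <- Mod(Cmat)
    P <- (P + t(P)) / 2; diag(P) <- 0
    mats[[paste0("PLV.", b)]] <- pmin(P, 1)
    L <- matrix(0, M, M)
    for (i in seq_len(M - 1L)) for (j in (i + 1L):M) {
      v <- pli(Phi[i, ], Phi[j, ])
      L[i, j] <- v; L[j, i] <- v
    }
    mats[[paste0("PLI.", b)]] <- L
    # S index: shared embeddings per channel
    Np <- N - (sp$d - 1L) * sp$tau
    theiler <- sp$tau * (sp$d - 1L)
    refs <- if (Np <= sp$max_ref) seq_len(Np) else
      unique(as.integer(round(seq(1L, Np, length.out = sp$max_ref))))
    parts <- lapply(seq_len(M), function(i)
      .embed_neighbors(.delay_embed(X[i, ], sp$d, sp$tau), sp$k, refs,
                       theiler))
    S <- matrix(0, M, M)
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i == j) next
      S[i, j] <- .s_from_parts(parts[[i]]$D, parts[[i]]$nn, parts[[j]]$nn)
    }
    mats[[paste0("S.", b)]] <- S
    # effective connectivity
    mats[[paste0("GC.", b)]] <- .gc_matrix(X, config$mar_order)
    model <- fit_mar(X, config$mar_order)
    fr <- seq(config$bands[[b]][1L], config$bands[[b]][2L],
              length.out = config$pdc_n_freqs) / fs
    Pd <- pdc_matrix(model, fr)
    diag(Pd) <- 0
    mats[[paste0("PDC.", b)]] <- Pd
  }
  order_keys <- as.vector(outer(config$metrics, bands,
                                function(m, b) paste0(m, ".", b)))
  structure(list(matrices = mats[order_keys], metrics = config$metrics,
                 bands = bands, M = M),
            class = "connectivity_tensor")
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  cat("Connectivity tensor: ", length(x$matrices), " matrices (",
      length(x$metrics), " metrics x ", length(x$bands), " bands), M = ",
      x$M, "\n", sep = "")
  invisible(x)
}
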