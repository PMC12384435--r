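test_that("analytic phase of a pure tone advances at 2 pi f rad/s", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  phi <- instantaneous_phase(cos(2 * pi * 10 * t))
  expect_true(all(phi > -pi & phi <= pi))
  core <- seq(round(0.1 * length(phi)), round(0.9 * length(phi)))
  dphi <- diff(phi[core])
  dphi <- (dphi + pi) %% (2 * pi) - pi            # wrap increments
  slope <- mean(dphi) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
  expect_error(instantaneous_phase(rep(3, 100)), "constant")
})

test_that("PLV matches direct evaluation on constructed phases", {
  phi <- runif(50, -pi, pi)
  expect_equal(plv(phi, phi), 1)
  expect_equal(plv(c(rep(0, 5), rep(pi, 5)), rep(0, 10)), 0)
  expect_equal(plv(c(rep(0, 5), rep(pi / 2, 5)), rep(0, 10)),
               sqrt(2) / 2)
  expect_error(plv(phi, phi[-1]), "lengths differ")
})

test_that("PLI matches the signed-difference rule", {
  expect_equal(pli(rep(0.3, 8), rep(0, 8)), 1)
  expect_equal(pli(rep(1, 8), rep(1, 8)), 0)              # sign(0) = 0
  expect_equal(pli(c(0.3, 0.1, -0.2, -0.4), rep(0, 4)), 0)
  expect_equal(pli(c(rep(0, 5), rep(pi, 5)), rep(0, 10)), 0)  # antipodal
})

test_that("PLV and PLI agree with naive summation oracles to 1e-12", {
  set.seed(21)
  for (rep_i in 1:10) {
    px <- runif(10, -pi, pi)
    py <- runif(10, -pi, pi)
    plv_oracle <- {
      re <- 0; im <- 0
      for (n in 1:10) {
        re <- re + cos(px[n] - py[n]); im <- im + sin(px[n] - py[n])
      }
      sqrt((re / 10)^2 + (im / 10)^2)
    }
    pli_oracle <- {
      s <- 0
      for (n in 1:10) s <- s + sign(sin(px[n] - py[n]))
      abs(s / 10)
    }
    expect_equal(plv(px, py), plv_oracle, tolerance = 1e-12)
    expect_equal(pli(px, py), pli_oracle, tolerance = 1e-12)
  }
})

test_that("S index is 1 for self-synchrony and bounded by 1", {
  set.seed(31)
  x <- rnorm(300)
  expect_equal(s_index(x, x), 1)
  for (i in 1:10) {
    a <- rnorm(120); b <- rnorm(120)
    s <- s_index(a, b)
    expect_lte(s, 1)
    expect_gte(s, 0)
  }
  expect_error(s_index(rnorm(8), rnorm(8), d = 3, k = 4), "too short")
})

test_that("S index matches a naive direct-summation oracle on tiny input", {
  # independent brute-force oracle with the same embedding conventions
  s_oracle <- function(x, y, d, tau, k) {
    embed_o <- function(z) {
      n0 <- (d - 1) * tau + 1
      t(vapply(n0:length(z), function(n)
        z[n - (0:(d - 1)) * tau], numeric(d)))
    }
    Ex <- embed_o(x); Ey <- embed_o(y)
    Np <- nrow(Ex); th <- tau * (d - 1)
    nn_of <- function(E, n) {
      dd <- vapply(seq_len(Np), function(j)
        if (abs(j - n) <= th) Inf else sum((E[n, ] - E[j, ])^2), 0)
      order(dd)[seq_len(k)]
    }
    ratios <- vapply(seq_len(Np), function(n) {
      dx <- vapply(seq_len(Np), function(j) sum((Ex[n, ] - Ex[j, ])^2), 0)
      mean(dx[nn_of(Ex, n)]) / mean(dx[nn_of(Ey, n)])
    }, 0)
    mean(ratios)
  }
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(s_index(x, y, d = 2, tau = 1, k = 2),
                 s_oracle(x, y, 2, 1, 2), tolerance = 1e-12)
  }
})

test_that("S index increases as one series is mixed towards the other", {
  set.seed(51)
  x <- rnorm(2000); noise <- rnorm(2000)
  s_indep <- s_index(x, noise, max_ref = 200)
  s_half <- s_index(x, 0.7 * x + 0.3 * noise, max_ref = 200)
  s_self <- s_index(x, x, max_ref = 200)
  expect_lt(s_indep, 0.9 * s_self)
  expect_true(s_indep < s_half && s_half < s_self)
})

test_that("MAR fit recovers known VAR(1) coefficients", {
  A <- matrix(c(0.5, 0.1, 0.2, 0.3), 2, byrow = TRUE)
  set.seed(61)
  N <- 5000
  X <- matrix(0, 2, N)
  for (t in 2:N) X[, t] <- A %*% X[, t - 1] + rnorm(2, sd = 0.1)
  fit <- fit_mar(X, p = 1)
  expect_lt(max(abs(fit$A[[1]] - A)), 0.05)
  expect_equal(fit$n_effective, N - 1L)
  expect_lt(fit$spectral_radius, 1)
  expect_true(isSymmetric(fit$sigma))
  expect_true(all(eigen(fit$sigma, only.values = TRUE)$values > -1e-12))
})

test_that("MAR fit on white noise gives near-zero coefficients", {
  set.seed(62)
  X <- matrix(rnorm(2 * 4000), 2)
  fit <- fit_mar(X, p = 2)
  # 3 standard errors, SE ~ sd/sqrt(N) for standardized regressors
  expect_lt(max(abs(unlist(fit$A))), 3.5 / sqrt(fit$n_effective))
})

test_that("degenerate MAR inputs are rejected", {
  expect_error(fit_mar(matrix(rnorm(10), 2), p = 10), "too few samples")
  X <- matrix(rnorm(400), 2)
  X <- rbind(X, X[1, ])                  # duplicated channel
  expect_error(fit_mar(X, p = 2), "rank-deficient")
})

test_that("Granger causality is null for independent noise", {
  set.seed(71)
  xa <- rnorm(2000); xb <- rnorm(2000)
  gc_obs <- granger_pairwise(xa, xb, p = 5)
  # permutation null: circularly shift the candidate cause
  perms <- vapply(1:100, function(i) {
    k <- sample(100:1900, 1)
    granger_pairwise(xa, c(xb[(k + 1):2000], xb[1:k]), p = 5)
  }, 0)
  expect_lt(gc_obs, quantile(perms, 0.95) * 1.5 + 1e-4)
  expect_gte(gc_obs, 0)
})

test_that("Granger causality recovers coupling direction and limit case", {
  set.seed(72)
  xb <- rnorm(2000)
  xa <- 0.8 * c(0, xb[-2000]) + rnorm(2000, sd = 0.5)
  expect_gt(granger_pairwise(xa, xb), granger_pairwise(xb, xa))
  # noiseless unit-lag copy: full-model variance collapses to the floor
  y <- c(0, xb[-2000])
  gc_big <- granger_pairwise(y, xb, p = 1)
  expect_true(is.finite(gc_big))
  expect_gt(gc_big, 10)
})

test_that("PDC columns are normalized and match a hand-evaluated VAR(1)", {
  A1 <- matrix(c(0.5, 0, 0.4, 0.5), 2, byrow = TRUE)
  model <- structure(list(p = 1L, A = list(A1), sigma = diag(2),
                          n_effective = 100L, M = 2L, spectral_radius = 0.5),
                     class = "mar_model")
  # hand evaluation at f = 0: Abar = I - A1
  Abar <- diag(2) - A1
  cn <- sqrt(colSums(Abar^2))
  want <- abs(Abar) / rep(cn, each = 2)
  got <- pdc_matrix(model, 0)
  expect_equal(got, want, tolerance = 1e-10)
  # column normalization at every frequency
  arr <- pdc_matrix(model, seq(0.05, 0.45, by = 0.05), average = FALSE)
  for (fi in seq_len(dim(arr)[3]))
    expect_equal(colSums(arr[, , fi]^2), c(1, 1), tolerance = 1e-9)
  # no cross-channel coefficients -> zero off-diagonal PDC
  modd <- model
  modd$A <- list(diag(0.5, 2))
  pd <- pdc_matrix(modd, c(0.1, 0.2))
  expect_equal(pd[1, 2], 0)
  expect_equal(pd[2, 1], 0)
})

test_that("PDC recovers seeded coupling direction across seeded runs", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    N <- 2000
    X <- matrix(0, 2, N)
    innov <- matrix(rnorm(2 * N), 2)
    for (t in 2:N) {
      X[1, t] <- 0.3 * X[1, t - 1] + innov[1, t]
      X[2, t] <- 0.3 * X[2, t - 1] + 0.5 * X[1, t - 1] + innov[2, t]
    }
    pd <- pdc_matrix(fit_mar(X, p = 2), seq(0.05, 0.45, length.out = 10))
    if (pd[2, 1] > pd[1, 2]) hits <- hits + 1L   # coupling 1 -> 2
  }
  expect_gte(hits, 19L)
})

test_that("the per-segment tensor has 15 matrices with declared ranges", {
  fx <- fixture_segment_bands_7ch()
  tensor <- connectivity_tensor(fx$bands, pipeline_config("7ch"))
  expect_length(tensor$matrices, 15L)
  expect_true(all(vapply(tensor$matrices, function(m)
    all(dim(m) == c(7, 7)), TRUE)))
  for (key in names(tensor$matrices)) {
    m <- tensor$matrices[[key]]
    expect_true(all(diag(m) == 0), info = key)
    metric <- sub("\\..*$", "", key)
    if (metric %in% c("PLV", "PLI")) {
      expect_identical(m, t(m), info = key)
      expect_true(all(m >= 0 & m <= 1), info = key)
    }
    if (metric == "S") expect_true(all(m >= 0 & m <= 1 + 1e-12), info = key)
    if (metric == "GC") expect_true(all(m >= 0), info = key)
    if (metric == "PDC") expect_true(all(m >= 0 & m <= 1), info = key)
  }
  expect_error(connectivity_tensor(fx$bands[c("theta", "alpha")],
                                   pipeline_config("7ch")),
               "missing band")
})
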