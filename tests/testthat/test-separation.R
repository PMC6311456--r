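test_that("a minimum-phase kernel is inverted exactly", {
  # pure exponential decay discretized at the frame rate: all zeros of the
  # tap polynomial lie outside the unit circle, so back-substitution is the
  # exact stable inverse
  kd <- structure(list(t = seq(0, 2, by = 0.05), w = 0.9^(0:40), t_peak = 0,
                       t_half = 0.05 * log(2) / log(1 / 0.9), dt = 0.05,
                       rise = "linear"),
                  class = "indicator_kernel")
  set.seed(2)
  S <- matrix(rbinom(3 * 2000, 1, 0.02), 3) * matrix(runif(6000, 0.5, 2), 3)
  Y <- refilter(S, kd)
  Z <- inverse_filter(Y, kd)
  expect_lt(max(abs(Z$values - S)), 1e-6)
  expect_equal(attr(Z, "boundary_frames"), 0L)
})

test_that("the GCaMP kernel round trip is exact away from the trace end", {
  kern <- gcamp_kernel()
  k20 <- kernel_at_rate(kern, 20)
  set.seed(3)
  S <- matrix(rbinom(4 * 3000, 1, 0.02), 4) * matrix(runif(12000, 0.5, 2), 4)
  Y <- refilter(S, k20)
  expect_warning(Z <- inverse_filter(Y, k20), "minimum phase")
  b <- attr(Z, "boundary_frames")
  expect_gt(b, 0)
  interior <- seq_len(3000 - b)
  expect_lt(max(abs(Z$values - S)[, interior]), 1e-6)
  # refiltering the deconvolved signal returns the recording
  Y2 <- refilter(Z, k20)
  expect_lt(max(abs(Y2$values - Y$values)[, interior]), 1e-6)
  # linearity of the inverse filter
  Zs <- suppressWarnings(inverse_filter(
    trace_matrix(2 * Y$values, 20, "fiber"), k20))
  expect_equal(Zs$values, 2 * Z$values, tolerance = 1e-9)
})

test_that("refiltering an impulse reproduces the framed kernel", {
  kern <- gcamp_kernel()
  k20 <- kernel_at_rate(kern, 20)
  imp <- matrix(0, 1, 100)
  imp[1, 1] <- 1
  out <- refilter(imp, k20)
  expect_equal(out$values[1, seq_along(k20$w)], k20$w, tolerance = 1e-12)
  expect_equal(refilter(matrix(0, 2, 50), k20)$values, matrix(0, 2, 50))
})

test_that("whitening produces identity covariance and handles rank loss", {
  set.seed(4)
  Z <- diag(runif(5, 1, 4)) %*% matrix(rnorm(5 * 1000), 5) + runif(5, 0, 2)
  wh <- whiten(Z)
  C <- cov(t(wh$Zw))
  expect_lt(max(abs(C - diag(nrow(C)))), 1e-8)
  # the transform is returned and reproduces the output
  expect_equal(wh$V %*% Z, wh$Zw)
  # duplicated channel exercises the rank-reduction path
  Zdup <- rbind(Z, Z[1, ])
  expect_warning(whd <- whiten(Zdup), "rank")
  expect_equal(whd$rank, 5)
  expect_error(whiten(matrix(1, 1, 10)), "2 channels")
  expect_error(whiten(matrix(1, 5, 4)), "more frames")
})

test_that("already-separated non-negative sources are left intact", {
  X <- make_sources(3, T = 6000, seed = 31)
  res <- nonneg_ica(X, seed = 1)
  expect_gte(best_perm_min_r2(res$S_est, X), 0.99)
  expect_true(all(diff(res$J) <= 1e-12))
})

test_that("square non-negative mixtures are recovered by rotation", {
  X <- make_sources(3, T = 6000, seed = 32)
  A <- withr::with_seed(5, matrix(runif(9, 0.2, 1), 3) + diag(3))
  res <- nonneg_ica(A %*% X, seed = 2)
  expect_gte(best_perm_min_r2(res$S_est, X), 0.99)
  # descent property and orthonormality of the unmixing rotation
  expect_true(all(diff(res$J) <= 1e-12))
  expect_lt(max(abs(res$W %*% t(res$W) - diag(3))), 1e-8)
  expect_lte(res$J[length(res$J)], res$J[1])
})

test_that("recovery holds across sizes and seeds for well-grounded mixtures", {
  for (n in c(2, 3, 5)) {
    ok <- 0
    for (s in 1:20) {
      X <- make_sources(n, T = 6000, rate = 0.4, seed = 100 * n + s)
      A <- withr::with_seed(200 * n + s,
                            matrix(runif(n * n, 0.2, 1), n) + diag(n))
      res <- suppressWarnings(nonneg_ica(A %*% X, seed = s,
                                         max_iter = 1000))
      if (best_perm_min_r2(res$S_est, X) >= 0.99) ok <- ok + 1
    }
    expect_gte(ok, 18)   # >= 90% of 20 seeded runs
  }
})

test_that("channel permutation does not change the reachable objective", {
  X <- make_sources(3, T = 6000, seed = 33)
  A <- withr::with_seed(6, matrix(runif(9, 0.2, 1), 3) + diag(3))
  Z <- A %*% X
  J1 <- tail(nonneg_ica(Z, seed = 3)$J, 1)
  J2 <- tail(nonneg_ica(Z[c(2, 3, 1), ], seed = 3)$J, 1)
  expect_equal(J1, J2, tolerance = 1e-6)
})

test_that("the axis-pair reference optimizer reaches the same objective", {
  X <- make_sources(2, T = 2000, seed = 34)
  A <- withr::with_seed(7, matrix(runif(4, 0.2, 1), 2) + diag(2))
  Z <- A %*% X
  J_geo <- tail(nonneg_ica(Z, seed = 4)$J, 1)
  J_jac <- tail(nonneg_ica_jacobi(Z, sweeps = 40, seed = 4)$J, 1)
  expect_lt(abs(J_geo - J_jac), 1e-4 * max(J_jac, 1e-8) + 1e-8)
})

test_that("the end-to-end pipeline separates the toy mixture", {
  toy <- make_toy_fixture()
  mm <- build_mixing_matrix(toy$layout, toy$population, toy$profile)
  kern <- gcamp_kernel()
  spikes <- simulate_spike_trains(mm$M |> ncol(), 0.4, 240, seed = 55)
  X <- convolve_and_frame(spikes, kern, 20)
  Y <- mix_traces(mm, X)
  res <- suppressWarnings(separate_sources(Y, kern, seed = 5))
  # compare over the boundary-trimmed window the separation evaluates
  Tm <- ncol(res$S_fluor$values)
  Xfg <- X$values[toy$fg_idx, seq_len(Tm), drop = FALSE]
  m <- match_components(res$S_fluor, Xfg, 0.6)
  expect_gte(sum(m$matched), 3)
  expect_equal(length(unique(m$best_true[m$matched])), 3)
  # determinism under a fixed seed
  res2 <- suppressWarnings(separate_sources(Y, kern, seed = 5))
  expect_identical(res$S_est, res2$S_est)
  expect_error(separate_sources(Y, kern, n_components = 10), "more")
})
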