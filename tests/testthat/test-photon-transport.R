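test_that("launch directions follow the truncated-normal NA cone", {
  props <- optical_preset("tissue490")
  # degenerate cone: NA = 0 goes straight down the axis
  d0 <- withr::with_seed(1, sample_launch_direction(
    launch_spec(numerical_aperture = 0), props, n = 100))
  expect_equal(d0, matrix(rep(c(0, 0, 1), each = 100), ncol = 3))
  # polar angle distribution matches a direct draw of the stated
  # |N(0, asin(NA/n)^2)| truncated at pi/2
  n <- 1e5
  d <- withr::with_seed(2, sample_launch_direction(launch_spec(), props, n))
  expect_equal(rowSums(d^2), rep(1, n), tolerance = 1e-12)
  theta <- acos(pmin(1, d[, 3]))
  sigma <- asin(0.377 / 1.36)
  oracle <- withr::with_seed(3, abs(rnorm(n, 0, sigma)))
  oracle <- oracle[oracle < pi / 2]
  se <- sqrt(sd(theta)^2 / n + sd(oracle)^2 / length(oracle))
  expect_lt(abs(mean(theta) - mean(oracle)), 3 * se)
  se_sd <- sqrt(sd(theta)^2 / (2 * n) + sd(oracle)^2 / (2 * length(oracle)))
  expect_lt(abs(sd(theta) - sd(oracle)), 3 * se_sd)
  # NA must stay below the medium index
  expect_error(sample_launch_direction(
    launch_spec(numerical_aperture = 1.5), props), "smaller")
})

test_that("free-path sampling is exponential with mean 1/mu_t", {
  expect_equal(sample_step_length(1, u = exp(-1)), 1.0)
  mu_t <- 20.337
  x <- withr::with_seed(4, sample_step_length(mu_t, n = 1e5))
  expect_lt(abs(mean(x) - 1 / mu_t), 3 * sd(x) / sqrt(1e5))
  expect_error(sample_step_length(0), "positive")
})

test_that("Henyey-Greenstein deflection cosine has first moment g", {
  n <- 1e5
  for (g in c(0, 0.5, 0.9)) {
    inc <- c(0, 0, 1)
    out <- withr::with_seed(10 + round(10 * g),
                            sample_scatter_direction(g, inc, n = n))
    ct <- out[, 3]   # cosine with incoming +z
    expect_lt(abs(mean(ct) - g), 3 * sd(ct) / sqrt(n))
  }
  # forward-scattering limit
  out <- withr::with_seed(5, sample_scatter_direction(1 - 1e-9, c(0, 0, 1),
                                                      n = 100))
  expect_gt(min(out[, 3]), 1 - 1e-6)
  # scattering about a tilted axis preserves the HG cosine
  inc <- c(1, 2, -1) / sqrt(6)
  out <- withr::with_seed(6, sample_scatter_direction(0.9, inc, n = 1e4))
  ct <- out %*% inc
  expect_lt(abs(mean(ct) - 0.9), 3 * sd(ct) / sqrt(1e4))
  expect_error(sample_scatter_direction(1.2, c(0, 0, 1)), "\\[-1, 1\\]")
})

test_that("packet weight is conserved to 1e-9 and fluence is non-negative", {
  prof <- test_profile("tissue490")
  ce <- conservation_error(prof)
  expect_lt(ce$relative_error, 1e-9)
  expect_true(all(prof$values >= 0))
  expect_equal(prof$n_packets, 1e5)
  expect_equal(prof$seed, 301L)
})

test_that("fluence simulation is reproducible under a fixed seed", {
  g <- voxel_grid(extent = 0.2, voxel_size = 0.01)
  a <- simulate_fluence(500, grid = g, seed = 99)
  b <- simulate_fluence(500, grid = g, seed = 99)
  expect_identical(a$values, b$values)
  c2 <- simulate_fluence(500, grid = g, seed = 100)
  expect_false(identical(a$values, c2$values))
})

test_that("peak fluence sits at the fiber tip and decays with distance", {
  prof <- test_profile("tissue490")
  pk <- which(prof$values == max(prof$values), arr.ind = TRUE)[1, ]
  ctr <- prof$grid$dims / 2
  expect_true(all(abs(pk - c(ctr[1], ctr[2], ctr[3])) <= 2))
  onax <- prof$values[ctr[1], ctr[2], ]
  z_up <- (ctr[3] + 1):prof$grid$dims[3]
  # monotone decay of the smoothed axial profile beyond the tip
  decim <- onax[z_up][seq(1, length(z_up), by = 10)]
  expect_true(all(diff(decim) < 0))
})

test_that("absorption-dominated media deposit essentially all weight", {
  props <- optical_properties(mu_a = 500, mu_s = 0.1, g = 0.9)
  g <- voxel_grid(extent = 0.2, voxel_size = 0.005)
  prof <- simulate_fluence(2000, props = props, grid = g, seed = 12)
  b <- prof$bookkeeping
  expect_lt(b$escaped / b$launched, 1e-6)
  pk <- which(prof$values == max(prof$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(pk - g$dims / 2) <= 1))
})

test_that("water-mode axial profile matches the ballistic closed form", {
  prof <- test_profile("water", n_packets = 1e5, seed = 302)
  h <- prof$grid$voxel_size
  sigma <- asin(0.377 / optical_preset("water")$n_medium)
  norm <- 2 * (pnorm(pi / 2, 0, sigma) - 0.5)
  half <- prof$grid$extent[1] / 2
  moment <- function(z, p) {
    th_max <- atan(half / z)
    stats::integrate(function(th) 2 * dnorm(th, 0, sigma) / norm /
                       cos(th)^p, 0, min(th_max, pi / 2 - 1e-9))$value
  }
  ctr <- prof$grid$dims[3] / 2
  for (slab_idx in ctr + c(10, 20, 30)) {
    z <- (slab_idx - 0.5) * h - half   # slab center above the tip plane
    # per-packet track length within the transverse slab
    measured <- sum(prof$values[, , slab_idx]) * h^3
    m1 <- moment(z, 1)
    se <- sqrt(max(moment(z, 2) - m1^2, 0) / prof$n_packets)
    expect_lt(abs(measured / h - m1), 3 * se + 1e-12)
  }
})

test_that("per-packet profiles converge as packet count grows", {
  g <- voxel_grid(extent = 0.2, voxel_size = 0.01)
  ref <- simulate_fluence(64000, grid = g, seed = 40,
                          props = optical_preset("water"))
  lo <- simulate_fluence(2000, grid = g, seed = 41,
                         props = optical_preset("water"))
  hi <- simulate_fluence(8000, grid = g, seed = 42,
                         props = optical_preset("water"))
  err_lo <- sqrt(mean((lo$values - ref$values)^2))
  err_hi <- sqrt(mean((hi$values - ref$values)^2))
  # quadrupling packets should roughly halve the RMS error
  expect_lt(err_hi / err_lo, 0.75)
  expect_gt(err_hi / err_lo, 0.3)
})

test_that("profiles are approximately axially symmetric", {
  prof <- test_profile("tissue490")
  ctr <- prof$grid$dims / 2
  slab <- prof$values[, , ctr[3] + 15]
  # compare the four axis-aligned quadrant sums against their mean
  i <- seq_len(ctr[1])
  q <- c(sum(slab[i, i]), sum(slab[rev(ctr[1] + i), i]),
         sum(slab[i, rev(ctr[2] + i)]), sum(slab[rev(ctr[1] + i),
                                              rev(ctr[2] + i)]))
  expect_lt(max(abs(q - mean(q))) / mean(q), 0.1)
})

test_that("physical scaling of fluence is linear in coupled power", {
  prof <- test_profile("tissue490")
  s1 <- scale_fluence(prof, 1.25)
  s2 <- scale_fluence(prof, 2.5)
  expect_equal(s2, 2 * s1)
  a <- vapply(c(1.25, 2.5, 5), function(p)
    contour_area(scale_fluence(prof, p), prof, level = 2.5), numeric(1))
  expect_true(all(diff(a) >= 0))
  expect_error(scale_fluence(prof, 0), "> 0")
})

test_that("the grid must contain the launch tip", {
  g <- voxel_grid(extent = 0.2, voxel_size = 0.01)
  expect_error(simulate_fluence(10, launch = launch_spec(tip = c(0, 0, 0.5)),
                                grid = g), "contain")
})
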