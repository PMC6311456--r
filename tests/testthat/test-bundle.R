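test_that("fiber splay sampling matches its normal model", {
  lay0 <- sample_fiber_positions(5, sigma_xy = 0, sigma_z = 0, seed = 1)
  expect_equal(max(abs(lay0$positions)), 0)
  lay <- sample_fiber_positions(1e4, sigma_xy = 0.150, seed = 2)
  for (ax in 1:2) {
    s <- sd(lay$positions[, ax])
    se <- 0.150 / sqrt(2 * 1e4)
    expect_lt(abs(s - 0.150), 3 * se)
  }
  expect_lt(abs(sd(lay$positions[, 3]) - 0.015), 3 * 0.015 / sqrt(2e4))
  expect_identical(sample_fiber_positions(100, seed = 7)$positions,
                   sample_fiber_positions(100, seed = 7)$positions)
  expect_error(sample_fiber_positions(0), ">= 1")
})

test_that("neuron counts follow density times volume", {
  pop <- sample_neuron_positions(250000, seed = 3)
  expect_equal(pop$n_neurons, 300000L)   # 250k/mm^3 in the 1.2-mm^3 box
  expect_equal(pop$volume, 1.2)
  expect_true(all(pop$positions >= matrix(pop$box[, 1], pop$n_neurons, 3,
                                          byrow = TRUE)))
  expect_true(all(pop$positions <= matrix(pop$box[, 2], pop$n_neurons, 3,
                                          byrow = TRUE)))
  empty <- sample_neuron_positions(0)
  expect_equal(empty$n_neurons, 0L)
  a <- sample_neuron_positions(1000, seed = 5)
  b <- sample_neuron_positions(1000, seed = 6)
  expect_equal(a$n_neurons, b$n_neurons)
  expect_false(identical(a$positions, b$positions))
})

test_that("trilinear profile lookup interpolates voxel centers exactly", {
  g <- voxel_grid(extent = 0.04, voxel_size = 0.01)  # 4x4x4
  vals <- array(seq_len(64), dim = c(4, 4, 4))
  prof <- structure(list(grid = g, values = vals, tip = c(0, 0, 0),
                         wavelength = NA), class = "fluence_profile")
  center <- function(i, j, k) g$origin + (c(i, j, k) - 0.5) * g$voxel_size
  # identity at a voxel center
  expect_equal(profile_lookup(prof, center(2, 3, 2)), vals[2, 3, 2])
  # midpoint of two voxel centers along x -> mean of the two values
  mid <- (center(2, 3, 2) + center(3, 3, 2)) / 2
  expect_equal(profile_lookup(prof, mid),
               mean(c(vals[2, 3, 2], vals[3, 3, 2])))
  # outside the grid -> 0
  expect_equal(profile_lookup(prof, c(1, 0, 0)), 0)
  # lookups are relative to the fiber tip
  expect_equal(profile_lookup(prof, center(2, 3, 2) + c(0.005, 0, 0),
                              tip = c(0.005, 0, 0)), vals[2, 3, 2])
})

test_that("mixing matrix obeys the excitation/collection identity", {
  # brute-force oracle on a small instance with the analytic profile
  prof <- gaussian_profile(sigma = 0.02, forward_offset = 0.01)
  lay <- sample_fiber_positions(3, sigma_xy = 0.02, seed = 21)
  pop <- structure(list(positions = matrix(rnorm(12, 0, 0.03), 4),
                        n_neurons = 4L, density = NA, box = NULL,
                        volume = NA, seed = NA_integer_),
                   class = "neuron_population")
  mm <- build_mixing_matrix(lay, pop, prof, prof, keep_factors = TRUE,
                            normalize = FALSE)
  gauss <- function(p, tip) {
    d <- p - tip
    d[3] <- d[3] - 0.01
    if (d[3] < -0.01) return(0)
    exp(-sum(d^2) / (2 * 0.02^2))
  }
  M_oracle <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    h_ij <- gauss(pop$positions[j, ], lay$positions[i, ])
    g_sum <- 0
    for (k in 1:3) g_sum <- g_sum + gauss(pop$positions[j, ],
                                          lay$positions[k, ])
    M_oracle[i, j] <- h_ij * g_sum
  }
  expect_equal(mm$M, M_oracle, tolerance = 1e-12)
  # factor identity M = h * colsum(g) holds exactly
  expect_equal(mm$M, mm$h * matrix(rowSums(mm$g), 3, 4, byrow = TRUE))
  expect_true(all(mm$M >= 0))
})

test_that("a single neuron immediately under a single fiber normalizes to 1", {
  prof <- test_profile("tissue490")
  lay <- sample_fiber_positions(1, sigma_xy = 0, sigma_z = 0, seed = 1)
  pk <- which(prof$values == max(prof$values), arr.ind = TRUE)[1, ]
  at_peak <- prof$grid$origin + (pk - 0.5) * prof$grid$voxel_size
  pop <- structure(list(positions = matrix(at_peak, 1), n_neurons = 1L,
                        density = NA, box = NULL, volume = NA,
                        seed = NA_integer_),
                   class = "neuron_population")
  mm <- build_mixing_matrix(lay, pop, prof, prof)
  expect_equal(mm$M[1, 1], 1, tolerance = 1e-9)
  # empty population degenerates to a zero-width matrix
  pop0 <- structure(list(positions = matrix(0, 0, 3), n_neurons = 0L,
                         density = NA, box = NULL, volume = NA,
                         seed = NA_integer_),
                    class = "neuron_population")
  expect_equal(dim(build_mixing_matrix(lay, pop0, prof, prof)$M), c(1L, 0L))
})

test_that("visibility counts shrink with threshold and the ge2 bound holds", {
  M <- rbind(c(0.5, 0.02, 0.001, 0), c(0.4, 0.03, 0, 0))
  vs <- visibility_stats(M, thresholds = c(0, 0.01, 0.1, 0.6))
  expect_true(all(diff(vs$visible_ge1) <= 0))
  expect_true(all(vs$visible_ge2 <= vs$visible_ge1))
  expect_equal(vs$visible_ge1[1], 3)   # threshold 0 counts all nonzero
  # single fiber, single bright neuron: nothing is seen twice
  vs1 <- visibility_stats(matrix(c(1, 0, 0), 1), thresholds = 0.01)
  expect_equal(vs1$visible_ge2, 0)
})

test_that("fiber contribution curves are normalized and non-increasing", {
  expect_equal(fiber_contribution_curve(matrix(c(4, 2, 1), 1), 3),
               c(1, 0.5, 0.25))
  one <- fiber_contribution_curve(matrix(c(3, 0, 0), 1), 3)
  expect_equal(one, c(1, 0, 0))
  M <- matrix(runif(50), 5)
  cur <- fiber_contribution_curve(M, 10)
  expect_equal(cur[1], 1)
  expect_true(all(diff(cur) <= 0))
  expect_error(fiber_contribution_curve(matrix(0, 2, 3)), "zero")
})

test_that("neuron collection curves are percentages of the strongest fiber", {
  expect_equal(neuron_collection_curve(matrix(c(10, 5), 2), 1, 2),
               c(100, 50))
  M <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(neuron_collection_curve(M, 1, 2), c(100, 0))
})

test_that("background splitting preserves total contribution weight", {
  M <- matrix(c(0.5, 0.3, 5e-5, 2e-5, 0.2, 1e-5), 2)
  mm <- structure(list(M = M, norm = 1, normalized = TRUE),
                  class = "mixing_matrix")
  sp <- split_background(mm, floor = 1e-4)
  expect_equal(sp$fg_idx, c(1L, 3L))
  expect_equal(sp$n_bg, 1L)
  expect_equal(sp$bg_weight, M[, 2])
  expect_equal(rowSums(sp$M_fg) + sp$bg_weight, rowSums(M))
})

test_that("streaming dominance matches the mixing-matrix computation", {
  prof <- test_profile("tissue490")
  lay <- sample_fiber_positions(10, seed = 81)
  pop <- sample_neuron_positions(5000, seed = 82)
  mm <- build_mixing_matrix(lay, pop, prof, prof)
  expect_equal(interface_dominance(lay, pop, prof, prof, chunk_size = 700L),
               brightness_dominance(mm), tolerance = 1e-10)
})

test_that("brightest neuron dominance is computed from sorted rows", {
  M <- rbind(c(4, 2, 1), c(3, 3, 0))
  # second/first ratios are 0.5 and 1: averaged curve point 0.75
  expect_equal(brightness_dominance(M), 100 * (1 / 0.75 - 1))
  # per-fiber ratios: 100% and 0% excess
  expect_equal(brightness_dominance(M, method = "per_fiber"), 50)
  expect_true(is.na(brightness_dominance(matrix(c(1, 0, 0), 1))))
})
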