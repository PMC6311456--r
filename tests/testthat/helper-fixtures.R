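# Shared fixtures. Monte Carlo profiles are memoised by cached_profile(),
# so every test file sees the same objects without recomputation.

test_profile <- function(preset = "tissue490", n_packets = 1e5, seed = 301) {
  cached_profile(preset, n_packets = n_packets, seed = seed)
}

# small deterministic bundle for interface tests
small_interface <- function(n_fibers = 20, n_neurons_density = 250000,
                            seed = 11) {
  list(layout = sample_fiber_positions(n_fibers, seed = seed),
       population = sample_neuron_positions(n_neurons_density,
                                            seed = seed + 1L))
}

# sparse non-negative well-grounded sources for separation tests
make_sources <- function(n, T = 6000, rate = 0.4, frame_rate = 20,
                         seed = 1) {
  kern <- gcamp_kernel()
  sp <- simulate_spike_trains(n, rate, T / frame_rate, seed = seed)
  convolve_and_frame(sp, kern, frame_rate)$values
}

# best assignment r2 between recovered and true sources (exhaustive over
# permutations; n <= 5 in tests)
best_perm_min_r2 <- function(S_est, S_true) {
  n <- nrow(S_true)
  r2 <- suppressWarnings(cor(t(S_est), t(S_true))^2)
  r2[!is.finite(r2)] <- 0
  perms <- gtools_permutations(n)
  max(apply(perms, 1, function(p) min(r2[cbind(seq_len(n), p)])))
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
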