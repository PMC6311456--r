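#' Scenario configuration
#'
#' All parameters of a full interface-modeling and source-separation
#' experiment, with desk-scale defaults: 1e6 photon packets, 100 fibers
#' with 150-um splay, 250,000 neurons/mm^3, 0.4-Hz spiking, GCaMP6f kernel,
#' 600-s recordings at 20 Hz, 5 iterations. `scale = "paper"` switches to
#' the 1e7-packet reference profile.
#'
#' @param ... Named overrides of the default fields.
#' @param seed Master seed; per-stage and per-iteration seeds are derived
#'   from it deterministically.
#' @param scale `"desk"` (default) or `"paper"` (1e7 packets).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(..., seed = 1L, scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  cfg <- list(
    # optics / photon transport
    n_packets = if (scale == "desk") 1e6 else 1e7,
    grid_extent = 1, voxel_size = 0.005,
    numerical_aperture = 0.377, core_diameter = 0.0051,
    # bundle interface
    n_fibers = 100L, sigma_xy = 0.150, sigma_z = 0.015,
    density = 250000, contribution_floor = 1e-4,
    # neural simulation
    rate = 0.4, duration = 600, frame_rate = 20, dt = 0.01,
    t_peak = 0.14, t_half = 0.32, n_background_samples = 100L,
    # separation
    n_components = NA, ica_max_iter = 1000L, ica_tol = 1e-8,
    ica_restarts = 1L,
    # evaluation
    r2_threshold = 0.6, tolerance_frames = 2L,
    r2_sweep = c(0.2, 0.4, 0.6, 0.8),
    # orchestration
    n_iterations = 5L, seed = as.integer(seed), scale = scale,
    toy = FALSE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  modifyList(cfg, over)
}

#' Save / load a scenario configuration as YAML
#'
#' @param config A `scenario_config`.
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(scenario_config, yaml::read_yaml(path))
}

# In-session memo cache for Monte Carlo profiles keyed by their parameters.
profile_cache_env <- new.env(parent = emptyenv())

#' Compute (or reuse) a preset sensitivity profile
#'
#' Memoises [simulate_fluence()] results within the session so that bundle
#' experiments sharing a profile do not repeat the Monte Carlo run.
#'
#' @param preset Optical preset name.
#' @param n_packets Packet count.
#' @param seed Profile seed.
#' @param grid_extent,voxel_size Grid geometry, mm.
#' @return A `fluence_profile`.
#' @export
cached_profile <- function(preset, n_packets = 1e6, seed = 1L,
                           grid_extent = 1, voxel_size = 0.005) {
  key <- paste(preset, n_packets, seed, grid_extent, voxel_size, sep = "|")
  if (!is.null(profile_cache_env[[key]])) return(profile_cache_env[[key]])
  prof <- simulate_fluence(n_packets,
                           launch = launch_spec(),
                           props = optical_preset(preset),
                           grid = voxel_grid(grid_extent, voxel_size),
                           seed = seed)
  profile_cache_env[[key]] <- prof
  prof
}

#' Deterministic toy fixture of the separation process
#'
#' A small configuration built for illustration and fast tests: three fibers
#' in a triangle, three foreground neurons each sitting near one fiber, and
#' a deterministic ring cloud of distant background neurons, with an
#' analytic Gaussian sensitivity profile in place of Monte Carlo transport.
#'
#' @param n_background Background cloud size (default 60).
#' @return List with `layout` (`fiber_layout`), `population`
#'   (`neuron_population`, foreground neurons first), `profile`
#'   (`gaussian_profile`), `fg_idx`.
#' @export
make_toy_fixture <- function(n_background = 60L) {
  tips <- rbind(c(-0.025, -0.015, 0), c(0.025, -0.015, 0), c(0, 0.028, 0))
  layout <- structure(list(positions = tips, n_fibers = 3L,
                           sigma_xy = NA_real_, sigma_z = NA_real_,
                           seed = NA_integer_),
                      class = "fiber_layout")
  fg <- tips + cbind(c(-0.008, 0.008, 0.004), c(-0.006, -0.006, 0.009),
                     c(0.012, 0.012, 0.012))
  ang <- 2 * pi * (seq_len(n_background) * 0.38196601)   # golden-angle ring
  rad <- 0.09 + 0.06 * (seq_len(n_background) %% 5) / 4
  bg <- cbind(rad * cos(ang), rad * sin(ang),
              0.02 + 0.01 * (seq_len(n_background) %% 3))
  pos <- rbind(fg, bg)
  colnames(pos) <- c("x", "y", "z")
  population <- structure(list(positions = pos,
                               n_neurons = nrow(pos),
                               density = NA_real_, box = NULL,
                               volume = NA_real_, seed = NA_integer_),
                          class = "neuron_population")
  list(layout = layout, population = population,
       profile = gaussian_profile(sigma = 0.02, forward_offset = 0.008),
       fg_idx = 1:3)
}

# Regenerate framed fluorescence for a subset of spike sources.
frame_subset <- function(spikes, idx, kernel, frame_rate) {
  sel <- spikes$src %in% idx
  remap <- match(spikes$src[sel], idx)
  factor <- as.integer(round(1 / spikes$dt / frame_rate))
  n_bins <- (spikes$n_bins %/% factor) * factor
  keep <- spikes$bin[sel] <= n_bins
  .spikes_to_frames(remap[keep], spikes$bin[sel][keep], length(idx),
                    n_bins, kernel$w, factor)
}

# One full simulate -> mix -> separate -> evaluate iteration.
run_iteration <- function(config, profiles, iter_seed) {
  seeds <- split_seed(iter_seed, 6L)
  if (isTRUE(config$toy)) {
    toy <- make_toy_fixture()
    layout <- toy$layout
    population <- toy$population
    exc_prof <- col_prof <- toy$profile
  } else {
    layout <- sample_fiber_positions(config$n_fibers, config$sigma_xy,
                                     config$sigma_z, seed = seeds[1])
    population <- sample_neuron_positions(config$density,
                                          seed = seeds[2])
    exc_prof <- profiles$excitation
    col_prof <- profiles$collection
  }
  mm <- build_mixing_matrix(layout, population, exc_prof, col_prof)
  dominance <- brightness_dominance(mm)
  vis1 <- visibility_stats(mm, thresholds = 0.01)
  split <- split_background(mm, config$contribution_floor)
  rm(mm)
  n_fg <- length(split$fg_idx)
  if (n_fg < 2) stop("fewer than two above-floor neurons; ",
                     "nothing to separate", call. = FALSE)
  kernel <- gcamp_kernel(config$t_peak, config$t_half, dt = config$dt)
  spikes <- simulate_spike_trains(n_fg, config$rate, config$duration,
                                  dt = config$dt, seed = seeds[3])
  # fiber recordings, accumulated over chunks of foreground neurons
  factor <- as.integer(round(1 / config$dt / config$frame_rate))
  n_frames <- (spikes$n_bins %/% factor)
  Yv <- matrix(0, nrow(split$M_fg), n_frames)
  chunk <- 2000L
  for (start in seq(1, n_fg, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_fg)
    Xch <- frame_subset(spikes, idx, kernel, config$frame_rate)
    Yv <- Yv + split$M_fg[, idx, drop = FALSE] %*% Xch
  }
  # shared background source: averaged activity of a sampled cohort
  if (any(split$bg_weight > 0) && config$n_background_samples > 0) {
    bg_spikes <- simulate_spike_trains(config$n_background_samples,
                                       config$rate, config$duration,
                                       dt = config$dt, seed = seeds[4])
    x_bg <- colMeans(convolve_and_frame(bg_spikes, kernel,
                                        config$frame_rate)$values)
    Yv <- Yv + outer(split$bg_weight, x_bg)
  }
  Y <- trace_matrix(Yv, config$frame_rate, "fiber")
  n_comp <- if (is.na(config$n_components)) nrow(Yv) else config$n_components
  sep <- separate_sources(Y, kernel, n_components = n_comp,
                          max_iter = config$ica_max_iter,
                          tol = config$ica_tol,
                          restarts = config$ica_restarts, seed = seeds[5])
  # match separated and raw traces against the above-floor truth over the
  # common (boundary-trimmed) evaluation window
  Tm <- ncol(sep$S_fluor$values)
  match_sep <- match_spikes_chunked(sep$S_fluor$values, spikes, kernel,
                                    config$frame_rate, config$r2_threshold)
  match_raw <- match_spikes_chunked(Yv[, seq_len(Tm), drop = FALSE], spikes,
                                    kernel, config$frame_rate,
                                    config$r2_threshold)
  ev_thr <- default_event_threshold(kernel, config$frame_rate)
  # regenerate only the matched true traces, one row per separated trace
  uniq <- sort(unique(match_sep$best_true))
  X_ref <- frame_subset(spikes, uniq, kernel,
                        config$frame_rate)[, seq_len(Tm), drop = FALSE]
  match_aligned <- match_sep
  match_aligned$best_true <- seq_len(nrow(match_sep))
  sweep <- threshold_sweep_roc(match_aligned, sep$S_fluor$values,
                               X_ref[match(match_sep$best_true, uniq), ,
                                     drop = FALSE],
                               r2_thresholds = config$r2_sweep,
                               event_threshold = ev_thr,
                               tolerance_frames = config$tolerance_frames)
  # control pool mirrors the size of the true matching pool
  ctrl <- random_control(sep$S_fluor, config$rate, kernel,
                         config$frame_rate, n_control = n_fg,
                         r2_threshold = config$r2_threshold,
                         event_threshold = ev_thr,
                         tolerance_frames = config$tolerance_frames,
                         seed = seeds[6])
  list(match_sep = match_sep, match_raw = match_raw,
       accuracy_sep = attr(match_sep, "accuracy"),
       accuracy_raw = attr(match_raw, "accuracy"),
       sweep = sweep, control = ctrl, n_foreground = n_fg,
       n_background = split$n_bg, dominance = dominance,
       visible_ge1 = vis1$visible_ge1, converged = sep$converged,
       iter_seed = iter_seed)
}

#' Run a full scenario
#'
#' Executes the complete pipeline (profile, bundle, simulate, separate,
#' evaluate) for `n_iterations` independent realizations and aggregates the
#' matching accuracies with and without separation, the r-squared threshold
#' sweep and the random-trace control.
#'
#' @param config A [scenario_config()].
#' @param profiles Optional list with precomputed `excitation` and
#'   `collection` fluence profiles (reused across iterations); computed from
#'   the config otherwise. Ignored by the toy fixture.
#' @param out_dir Optional directory; per-iteration and summary CSV tables
#'   plus the serialized result are written there.
#' @return A `scenario_result`: list with `iterations` (per-iteration
#'   results), `summary` (data frame), `improvement` (paired t-test), and
#'   the config.
#' @export
run_scenario <- function(config, profiles = NULL, out_dir = NULL) {
  stage_seeds <- split_seed(config$seed, 2L + config$n_iterations)
  if (!isTRUE(config$toy) && is.null(profiles)) {
    profiles <- list(
      excitation = cached_profile("tissue490", config$n_packets,
                                  stage_seeds[1], config$grid_extent,
                                  config$voxel_size),
      collection = cached_profile("tissue512", config$n_packets,
                                  stage_seeds[2], config$grid_extent,
                                  config$voxel_size))
  }
  iters <- lapply(seq_len(config$n_iterations), function(i)
    run_iteration(config, profiles, stage_seeds[2L + i]))
  summary <- data.frame(
    iteration = seq_along(iters),
    accuracy_raw = vapply(iters, `[[`, numeric(1), "accuracy_raw"),
    accuracy_sep = vapply(iters, `[[`, numeric(1), "accuracy_sep"),
    n_foreground = vapply(iters, `[[`, numeric(1), "n_foreground"),
    dominance_pct = vapply(iters, `[[`, numeric(1), "dominance"),
    visible_ge1_1pct = vapply(iters, `[[`, numeric(1), "visible_ge1"),
    control_mean_auc = vapply(iters, function(x) x$control$mean_auc,
                              numeric(1)),
    iter_seed = vapply(iters, `[[`, numeric(1), "iter_seed"))
  improvement <- if (config$n_iterations >= 2)
    paired_improvement_test(summary$accuracy_sep, summary$accuracy_raw)
  else NULL
  res <- structure(list(iterations = iters, summary = summary,
                        improvement = improvement, config = config),
                   class = "scenario_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    sweep_all <- do.call(rbind, lapply(seq_along(iters), function(i)
      cbind(iteration = i, iters[[i]]$sweep)))
    write.csv(sweep_all, file.path(out_dir, "r2_sweep.csv"),
              row.names = FALSE)
    write_artifact(res, file.path(out_dir, "scenario_result.rds"))
  }
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", nrow(x$summary), " iteration(s)\n", sep = "")
  cat("  accuracy raw  : ", sprintf("%.1f%% +/- %.1f",
      mean(x$summary$accuracy_raw), sd(x$summary$accuracy_raw)), "\n",
      sep = "")
  cat("  accuracy sep  : ", sprintf("%.1f%% +/- %.1f",
      mean(x$summary$accuracy_sep), sd(x$summary$accuracy_sep)), "\n",
      sep = "")
  if (!is.null(x$improvement))
    cat("  paired t-test : t = ", sprintf("%.3f", x$improvement$t),
        ", p = ", format.pval(x$improvement$p_value, digits = 3), "\n",
        sep = "")
  cat("  control AUC   : ",
      sprintf("%.3f", mean(x$summary$control_mean_auc)), "\n", sep = "")
  invisible(x)
}

#' Interface statistics across fiber counts
#'
#' Rebuilds the bundle interface for each fiber count (averaging over
#' several layout seeds with the splay held fixed) and tabulates neuron
#' visibility and brightness dominance.
#'
#' @param config A [scenario_config()] (supplies splay, density, profile
#'   parameters).
#' @param fiber_counts Vector of at least two fiber counts.
#' @param n_seeds Layout seeds per count (default 5).
#' @param thresholds Visibility thresholds (default
#'   `c(0.005, 0.01, 0.02, 0.05)`).
#' @param profiles Optional precomputed profiles, as in [run_scenario()].
#' @param out_csv Optional path for the CSV table.
#' @return Data frame with one row per (count, seed, threshold):
#'   `n_fibers`, `seed`, `threshold`, `visible_ge1`, `visible_ge2`,
#'   `mean_per_fiber`, `dominance_pct`.
#' @export
sweep_fibers <- function(config, fiber_counts, n_seeds = 5L,
                         thresholds = c(0.005, 0.01, 0.02, 0.05),
                         profiles = NULL, out_csv = NULL) {
  if (length(fiber_counts) < 2)
    stop("need at least two fiber counts", call. = FALSE)
  stage_seeds <- split_seed(config$seed, 2L)
  if (is.null(profiles)) {
    profiles <- list(
      excitation = cached_profile("tissue490", config$n_packets,
                                  stage_seeds[1], config$grid_extent,
                                  config$voxel_size),
      collection = cached_profile("tissue512", config$n_packets,
                                  stage_seeds[2], config$grid_extent,
                                  config$voxel_size))
  }
  seeds <- split_seed(config$seed + 1L, n_seeds)
  rows <- list()
  for (nf in fiber_counts) for (s in seq_len(n_seeds)) {
    layout <- sample_fiber_positions(nf, config$sigma_xy, config$sigma_z,
                                     seed = seeds[s])
    population <- sample_neuron_positions(config$density,
                                          seed = seeds[s] + 1L)
    mm <- build_mixing_matrix(layout, population, profiles$excitation,
                              profiles$collection)
    vs <- visibility_stats(mm, thresholds)
    vs$n_fibers <- nf
    vs$seed <- seeds[s]
    vs$dominance_pct <- brightness_dominance(mm)
    rows[[length(rows) + 1]] <- vs
    rm(mm)
  }
  out <- do.call(rbind, rows)
  out <- out[, c("n_fibers", "seed", "threshold", "visible_ge1",
                 "visible_ge2", "mean_per_fiber", "dominance_pct")]
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
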