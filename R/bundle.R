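#' Sample splayed fiber-tip positions
#'
#' Microfibers splay during insertion; tip positions are modeled as a
#' bivariate normal in the xy plane (default SD 150 um) with normally
#' distributed tip depths about the nominal tip plane (default SD 15 um).
#' All fiber axes are parallel to +z.
#'
#' @param n_fibers Number of fibers (>= 1).
#' @param sigma_xy Lateral splay SD, mm (default 0.150).
#' @param sigma_z Tip depth SD, mm (default 0.015).
#' @param seed Integer seed.
#' @return A `fiber_layout`: list with `positions` (`n x 3` matrix, mm),
#'   `n_fibers`, `sigma_xy`, `sigma_z`, `seed`.
#' @export
sample_fiber_positions <- function(n_fibers, sigma_xy = 0.150,
                                   sigma_z = 0.015, seed = 1L) {
  n_fibers <- as.integer(n_fibers)
  if (n_fibers < 1) stop("n_fibers must be >= 1", call. = FALSE)
  if (sigma_xy < 0 || sigma_z < 0) stop("SDs must be >= 0", call. = FALSE)
  pos <- with_seed(seed, cbind(rnorm(n_fibers, 0, sigma_xy),
                               rnorm(n_fibers, 0, sigma_xy),
                               rnorm(n_fibers, 0, sigma_z)))
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, n_fibers = n_fibers, sigma_xy = sigma_xy,
                 sigma_z = sigma_z, seed = as.integer(seed)),
            class = "fiber_layout")
}

#' Default neuron sampling box
#'
#' A box around the bundle large enough to include all regions of
#' non-negligible sensitivity: 1.2 x 1.2 mm laterally (4 sigma of splay plus
#' the sensitivity reach) by 5/6 mm axially, volume exactly 1.2 mm^3.
#'
#' @return A `3 x 2` matrix of (low, high) bounds per axis, mm.
#' @export
default_neuron_box <- function() {
  rbind(x = c(-0.6, 0.6), y = c(-0.6, 0.6), z = c(-0.25, 7 / 12))
}

#' Sample a uniform neuron population
#'
#' Point-source neurons distributed uniformly in a box; the count is
#' `round(density * volume)`.
#'
#' @param density Neurons per mm^3 (default 250000).
#' @param box `3 x 2` bounds matrix, mm (default [default_neuron_box()]).
#' @param seed Integer seed.
#' @return A `neuron_population`: list with `positions` (`n x 3`), `n_neurons`,
#'   `density`, `box`, `seed`.
#' @export
sample_neuron_positions <- function(density = 250000,
                                    box = default_neuron_box(), seed = 1L) {
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  widths <- box[, 2] - box[, 1]
  vol <- prod(widths)
  if (vol <= 0) stop("box volume must be > 0", call. = FALSE)
  n <- as.integer(round(density * vol))
  pos <- with_seed(seed, matrix(runif(3 * n), ncol = 3))
  pos <- sweep(sweep(pos, 2, widths, "*"), 2, box[, 1], "+")
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, n_neurons = n, density = density,
                 box = box, volume = vol, seed = as.integer(seed)),
            class = "neuron_population")
}

#' Excitation/collection mixing matrix of a fiber bundle
#'
#' Builds the non-negative fibers x neurons mixing matrix
#' `M[i, j] = h[i, j] * sum_k g[j, k]`, where `g[j, k]` is the excitation
#' sensitivity of fiber k at neuron j (490-nm profile) and `h[i, j]` the
#' collection sensitivity of fiber i at neuron j (512-nm profile, by optical
#' reciprocity). Values are normalized by the maximum round-trip signal of a
#' cell immediately under a single fiber (`h_peak * g_peak`), so a normalized
#' entry of 1 corresponds to that brightest-possible cell.
#'
#' @param layout A `fiber_layout`.
#' @param population A `neuron_population`.
#' @param excitation_profile Sensitivity profile at the excitation
#'   wavelength (from [simulate_fluence()] or [gaussian_profile()]).
#' @param collection_profile Sensitivity profile at the emission wavelength
#'   (default: same as excitation).
#' @param normalize Divide by the brightness anchor (default TRUE).
#' @param keep_factors Keep the `g` and `h` factor matrices (memory heavy at
#'   full population scale; default FALSE).
#' @param chunk_size Neurons processed per chunk (default 50000).
#' @return A `mixing_matrix`: list with `M` (fibers x neurons), the
#'   normalization constant `norm`, optionally `g` (neurons x fibers) and
#'   `h` (fibers x neurons), plus the inputs' seeds.
#' @export
build_mixing_matrix <- function(layout, population, excitation_profile,
                                collection_profile = excitation_profile,
                                normalize = TRUE, keep_factors = FALSE,
                                chunk_size = 50000L) {
  stopifnot(inherits(layout, "fiber_layout"),
            inherits(population, "neuron_population"))
  nf <- layout$n_fibers
  nn <- population$n_neurons
  norm_const <- profile_peak(collection_profile) *
    profile_peak(excitation_profile)
  M <- matrix(0, nf, nn)
  g_keep <- if (keep_factors) matrix(0, nn, nf)
  h_keep <- if (keep_factors) matrix(0, nf, nn)
  if (nn > 0) {
    tips <- layout$positions
    idx_chunks <- split(seq_len(nn), ceiling(seq_len(nn) / chunk_size))
    for (idx in idx_chunks) {
      pts <- population$positions[idx, , drop = FALSE]
      gch <- matrix(0, length(idx), nf)
      hch <- matrix(0, nf, length(idx))
      for (k in seq_len(nf)) {
        gch[, k] <- profile_lookup(excitation_profile, pts, tip = tips[k, ])
        hch[k, ] <- profile_lookup(collection_profile, pts, tip = tips[k, ])
      }
      exc_sum <- rowSums(gch)               # sum_k g[j, k]
      M[, idx] <- sweep(hch, 2, exc_sum, "*")
      if (keep_factors) {
        g_keep[idx, ] <- gch
        h_keep[, idx] <- hch
      }
    }
  }
  if (normalize) M <- M / norm_const
  structure(list(M = M, norm = norm_const, normalized = normalize,
                 g = g_keep, h = h_keep,
                 layout_seed = layout$seed, population_seed = population$seed),
            class = "mixing_matrix")
}

#' Split a mixing matrix into foreground neurons and aggregated background
#'
#' Neurons whose strongest normalized contribution to any fiber falls below
#' `floor` are aggregated into a single shared background source per fiber
#' (weight = summed sub-floor contributions), keeping trace simulation at
#' desk scale while preserving background fluorescence.
#'
#' @param mm A normalized `mixing_matrix`.
#' @param floor Contribution floor on the normalized column maximum
#'   (default 1e-4).
#' @return List with `M_fg` (fibers x foreground neurons), `fg_idx`
#'   (foreground column indices), `bg_weight` (per-fiber background weight)
#'   and `n_bg` (number of aggregated neurons).
#' @export
split_background <- function(mm, floor = 1e-4) {
  stopifnot(inherits(mm, "mixing_matrix"))
  if (ncol(mm$M) == 0)
    return(list(M_fg = mm$M, fg_idx = integer(0),
                bg_weight = rep(0, nrow(mm$M)), n_bg = 0L))
  colmax <- apply(mm$M, 2, max)
  fg <- which(colmax >= floor)
  bg <- which(colmax < floor)
  bg_weight <- if (length(bg)) rowSums(mm$M[, bg, drop = FALSE])
               else rep(0, nrow(mm$M))
  list(M_fg = mm$M[, fg, drop = FALSE], fg_idx = fg,
       bg_weight = bg_weight, n_bg = length(bg))
}

#' Neuron visibility statistics of the interface
#'
#' Counts neurons whose normalized fluorescence contribution to at least one
#' (and at least two) fibers exceeds each threshold, plus per-fiber counts of
#' visible neurons.
#'
#' @param M Normalized mixing matrix (fibers x neurons) or a `mixing_matrix`.
#' @param thresholds Contribution thresholds on the normalized brightness
#'   scale (default `c(0.005, 0.01, 0.02, 0.05)`; only the 1% level is a
#'   reference value, the others are illustrative).
#' @return Data frame with columns `threshold`, `visible_ge1`, `visible_ge2`,
#'   `mean_per_fiber`.
#' @export
visibility_stats <- function(M, thresholds = c(0.005, 0.01, 0.02, 0.05)) {
  if (inherits(M, "mixing_matrix")) M <- M$M
  out <- lapply(thresholds, function(th) {
    vis <- M > th
    nvis <- colSums(vis)
    data.frame(threshold = th,
               visible_ge1 = sum(nvis >= 1),
               visible_ge2 = sum(nvis >= 2),
               mean_per_fiber = mean(rowSums(vis)))
  })
  do.call(rbind, out)
}

#' Average per-fiber neuron contribution curve
#'
#' For each fiber, the contributions of its neurons sorted in descending
#' order and normalized to the brightest neuron; averaged across fibers.
#' All-zero fiber rows are excluded.
#'
#' @param M Mixing matrix (fibers x neurons) or `mixing_matrix`.
#' @param n_neurons Curve length (default 50).
#' @return Numeric vector of length `n_neurons`, starting at 1,
#'   non-increasing.
#' @export
fiber_contribution_curve <- function(M, n_neurons = 50) {
  if (inherits(M, "mixing_matrix")) M <- M$M
  rows <- which(apply(M, 1, max) > 0)
  if (!length(rows)) stop("all fiber rows are zero", call. = FALSE)
  curves <- vapply(rows, function(i) {
    v <- sort(M[i, ], decreasing = TRUE)[seq_len(n_neurons)]
    v[is.na(v)] <- 0
    v / v[1]
  }, numeric(n_neurons))
  rowMeans(curves)
}

#' Average per-neuron fiber collection curve
#'
#' For the `n_brightest` neurons (ranked by their strongest round-trip
#' contribution), each neuron's per-fiber contributions sorted in descending
#' order and normalized so that the strongest fiber is 100%; averaged across
#' the selected neurons.
#'
#' @param M Mixing matrix (fibers x neurons) or `mixing_matrix`.
#' @param n_brightest Number of brightest neurons to evaluate (default 50).
#' @param n_fibers Curve length (default `min(10, nrow(M))`).
#' @return Numeric vector in percent, starting at 100, non-increasing.
#' @export
neuron_collection_curve <- function(M, n_brightest = 50, n_fibers = NULL) {
  if (inherits(M, "mixing_matrix")) M <- M$M
  if (is.null(n_fibers)) n_fibers <- min(10L, nrow(M))
  colmax <- apply(M, 2, max)
  keep <- order(colmax, decreasing = TRUE)[seq_len(min(n_brightest, ncol(M)))]
  keep <- keep[colmax[keep] > 0]
  if (!length(keep)) stop("no neuron has a nonzero contribution", call. = FALSE)
  curves <- vapply(keep, function(j) {
    v <- sort(M[, j], decreasing = TRUE)[seq_len(n_fibers)]
    v[is.na(v)] <- 0
    100 * v / v[1]
  }, numeric(n_fibers))
  rowMeans(curves)
}

#' Excess brightness of the dominant neuron per fiber
#'
#' How much brighter the dominant neuron is than the runner-up: the
#' percentage by which the brightest neuron's contribution to a fiber
#' exceeds the second brightest. The default `"curve"` method reads the
#' excess off the fiber-averaged normalized contribution curve (each
#' fiber's sorted contributions normalized to its brightest neuron, then
#' averaged across fibers), the convention of the interface-statistics
#' plots; `"per_fiber"` instead averages the per-fiber ratios
#' `100 * (M_first / M_second - 1)`, which is systematically larger
#' because occasional strongly dominated fibers inflate the mean ratio.
#' Fibers with fewer than two contributing neurons (normalized brightness
#' at or above `floor`) are excluded.
#'
#' @param M Normalized mixing matrix (fibers x neurons) or `mixing_matrix`.
#' @param floor Contribution threshold on the normalized brightness scale
#'   (default 0.01, the visibility convention).
#' @param method `"curve"` (default) or `"per_fiber"`.
#' @return Mean excess brightness in percent (scalar).
#' @export
brightness_dominance <- function(M, floor = 0.01,
                                 method = c("curve", "per_fiber")) {
  method <- match.arg(method)
  if (inherits(M, "mixing_matrix")) M <- M$M
  second <- apply(M, 1, function(row) {
    v <- sort(row[row >= floor], decreasing = TRUE)
    if (length(v) < 2) return(NA_real_)
    v[2] / v[1]
  })
  if (all(is.na(second))) return(NA_real_)
  if (method == "curve") 100 * (1 / mean(second, na.rm = TRUE) - 1)
  else mean(100 * (1 / second - 1), na.rm = TRUE)
}

#' Brightness dominance computed without materializing the mixing matrix
#'
#' Streaming variant of [brightness_dominance()] for large bundles: neuron
#' chunks are looked up against the profiles and only each fiber's two
#' largest normalized contributions are retained, so memory stays
#' independent of the population size.
#'
#' @inheritParams build_mixing_matrix
#' @inheritParams brightness_dominance
#' @param chunk_size Neurons per chunk (default 20000).
#' @return Mean excess brightness in percent, as [brightness_dominance()].
#' @export
interface_dominance <- function(layout, population, excitation_profile,
                                collection_profile = excitation_profile,
                                floor = 0.01, method = c("curve",
                                                         "per_fiber"),
                                chunk_size = 20000L) {
  method <- match.arg(method)
  nf <- layout$n_fibers
  norm_const <- profile_peak(collection_profile) *
    profile_peak(excitation_profile)
  top1 <- rep(0, nf)
  top2 <- rep(0, nf)
  tips <- layout$positions
  nn <- population$n_neurons
  for (start in seq(1, nn, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, nn)
    pts <- population$positions[idx, , drop = FALSE]
    gch <- matrix(0, length(idx), nf)
    hch <- matrix(0, nf, length(idx))
    for (k in seq_len(nf)) {
      gch[, k] <- profile_lookup(excitation_profile, pts, tip = tips[k, ])
      hch[k, ] <- profile_lookup(collection_profile, pts, tip = tips[k, ])
    }
    Mch <- sweep(hch, 2, rowSums(gch), "*") / norm_const
    for (i in seq_len(nf)) {
      v <- sort(c(top1[i], top2[i], Mch[i, Mch[i, ] >= floor]),
                decreasing = TRUE)
      top1[i] <- v[1]
      top2[i] <- if (length(v) > 1) v[2] else 0
    }
  }
  second <- ifelse(top2 >= floor & top1 > 0, top2 / top1, NA_real_)
  if (all(is.na(second))) return(NA_real_)
  if (method == "curve") 100 * (1 / mean(second, na.rm = TRUE) - 1)
  else mean(100 * (1 / second - 1), na.rm = TRUE)
}
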