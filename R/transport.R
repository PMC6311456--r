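#' Sample photon launch directions
#'
#' Draws unit direction vectors for packets leaving the fiber face. The polar
#' angle from the fiber axis follows `|N(0, sigma^2)|` truncated at pi/2 with
#' `sigma = asin(NA / n_medium)`; the azimuth is uniform on `[0, 2*pi)`.
#'
#' @param launch A [launch_spec()].
#' @param props An [optical_properties()]; supplies `n_medium`.
#' @param n Number of directions to draw.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sample_launch_direction <- function(launch, props, n = 1) {
  na <- launch$numerical_aperture
  if (na >= props$n_medium)
    stop("numerical aperture must be smaller than the medium index",
         call. = FALSE)
  sigma <- asin(na / props$n_medium)
  if (sigma == 0) {
    theta <- rep(0, n)
  } else {
    theta <- abs(rnorm(n, 0, sigma))
    while (any(bad <- theta >= pi / 2))
      theta[bad] <- abs(rnorm(sum(bad), 0, sigma))
  }
  phi <- runif(n, 0, 2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Sample exponential free-path lengths
#'
#' Step lengths between photon interactions: `-log(U) / mu_t` with U uniform
#' on (0, 1].
#'
#' @param mu_t Total attenuation coefficient `mu_a + mu_s` (mm^-1), > 0.
#' @param n Number of draws.
#' @param u Optional uniform variates to transform (for closed-form checks).
#' @return Step lengths in mm.
#' @export
sample_step_length <- function(mu_t, n = 1, u = NULL) {
  if (!is.numeric(mu_t) || length(mu_t) != 1L || mu_t <= 0)
    stop("mu_t must be a positive scalar", call. = FALSE)
  if (is.null(u)) u <- runif(n)
  -log(u) / mu_t
}

#' Sample Henyey-Greenstein scattering directions
#'
#' Deflects incoming unit vectors so that the cosine of the deflection angle
#' follows the Henyey-Greenstein distribution with anisotropy `g` (whose mean
#' equals `g`); the azimuthal deflection is uniform.
#'
#' @param g Anisotropy in `[-1, 1]`.
#' @param incoming Unit 3-vector (or `n x 3` matrix) of incoming directions.
#' @param n Number of draws (recycled incoming if a single vector).
#' @return An `n x 3` matrix of unit vectors.
#' @export
sample_scatter_direction <- function(g, incoming, n = 1) {
  if (abs(g) > 1) stop("g must lie in [-1, 1]", call. = FALSE)
  if (is.null(dim(incoming))) incoming <- matrix(incoming, n, 3, byrow = TRUE)
  n <- nrow(incoming)
  u <- runif(n)
  if (abs(g) < 1e-8) {
    ct <- 2 * u - 1
  } else {
    f <- (1 - g^2) / (1 - g + 2 * g * u)
    ct <- pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- runif(n, 0, 2 * pi)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- incoming[i, ]
    d <- d / sqrt(sum(d^2))
    if (abs(d[3]) > 0.99999) {
      out[i, ] <- c(st[i] * cos(phi[i]), st[i] * sin(phi[i]),
                    ct[i] * sign(d[3]))
    } else {
      den <- sqrt(1 - d[3]^2)
      out[i, 1] <- st[i] * (d[1] * d[3] * cos(phi[i]) - d[2] * sin(phi[i])) /
        den + d[1] * ct[i]
      out[i, 2] <- st[i] * (d[2] * d[3] * cos(phi[i]) + d[1] * sin(phi[i])) /
        den + d[2] * ct[i]
      out[i, 3] <- -st[i] * cos(phi[i]) * den + d[3] * ct[i]
    }
    out[i, ] <- out[i, ] / sqrt(sum(out[i, ]^2))
  }
  out
}

#' Monte Carlo fluence sensitivity profile of a single fiber
#'
#' Launches weighted photon packets from the fiber core face and accumulates
#' the track-length fluence estimator per voxel. Packets take exponential
#' steps with `mu_t = mu_a + mu_s`, deposit the fraction `mu_a/mu_t` of their
#' weight at each interaction, scatter by Henyey-Greenstein otherwise, and
#' are terminated on leaving the grid or by Russian roulette (threshold
#' 1e-4, survival 0.1). Values are normalized per launched packet and per
#' voxel volume.
#'
#' @param n_packets Number of photon packets (>= 1). The reference bench
#'   scale is 1e7; 1e6 gives profiles adequate for interface modeling.
#' @param launch A [launch_spec()]; the tip must lie inside the grid.
#' @param props An [optical_properties()] or preset name.
#' @param grid A [voxel_grid()] (default 1-mm cube of 5-um voxels).
#' @param seed Integer seed; recorded in the result.
#' @return A `fluence_profile`: list with `grid`, `values` (3-D array,
#'   fluence per packet per mm^3 equivalent), `wavelength`, `n_packets`,
#'   `seed`, and a `bookkeeping` list (launched/deposited/escaped/roulette
#'   weights) satisfying conservation to < 1e-9 relative error.
#' @export
simulate_fluence <- function(n_packets, launch = launch_spec(),
                             props = optical_preset("tissue490"),
                             grid = voxel_grid(), seed = 1L) {
  if (is.character(props)) props <- optical_preset(props)
  stopifnot(inherits(launch, "launch_spec"), inherits(grid, "voxel_grid"))
  n_packets <- as.integer(n_packets)
  if (n_packets < 1) stop("n_packets must be >= 1", call. = FALSE)
  tip <- launch$tip
  lo <- grid$origin
  hi <- grid$origin + grid$extent
  if (any(tip < lo) || any(tip > hi))
    stop("grid does not contain the fiber tip", call. = FALSE)
  if (launch$numerical_aperture >= props$n_medium)
    stop("numerical aperture must be smaller than the medium index",
         call. = FALSE)
  sigma <- asin(launch$numerical_aperture / props$n_medium)
  res <- with_seed(seed, .mc_fluence(
    n_packets, props$mu_a, props$mu_s, props$g, sigma,
    tip[1], tip[2], tip[3], launch$core_diameter / 2,
    lo[1], lo[2], lo[3], grid$voxel_size,
    grid$dims[1], grid$dims[2], grid$dims[3],
    1e-4, 0.1))
  values <- array(res$values / (n_packets * grid$voxel_size^3), dim = grid$dims)
  structure(list(
    grid = grid,
    values = values,
    tip = tip,
    wavelength = attr(props, "wavelength"),
    props = props,
    launch = launch,
    n_packets = n_packets,
    seed = as.integer(seed),
    bookkeeping = list(launched = res$launched, deposited = res$deposited,
                       escaped = res$escaped, rr_killed = res$rr_killed,
                       rr_boost = res$rr_boost)
  ), class = "fluence_profile")
}

#' @export
print.fluence_profile <- function(x, ...) {
  cat("<fluence_profile> ", paste(x$grid$dims, collapse = "x"),
      " voxels of ", x$grid$voxel_size * 1000, " um, ",
      format(x$n_packets, big.mark = ","), " packets",
      if (!is.na(x$wavelength)) paste0(", ", x$wavelength, " nm"), "\n",
      sep = "")
  cat("  peak fluence ", format(max(x$values), digits = 4),
      " per packet/mm^2, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Energy-conservation summary of a fluence run
#'
#' @param profile A `fluence_profile`.
#' @return List with the weight ledger and the relative conservation error
#'   `|launched - deposited - escaped - (killed - boost)| / launched`.
#' @export
conservation_error <- function(profile) {
  b <- profile$bookkeeping
  resid <- b$rr_killed - b$rr_boost
  err <- abs(b$launched - b$deposited - b$escaped - resid) / b$launched
  c(b, list(roulette_residual = resid, relative_error = err))
}

#' Scale a per-packet fluence profile to physical excitation intensity
#'
#' @param profile A `fluence_profile` (values per launched packet).
#' @param coupled_power_uW Optical power coupled into the fiber, in uW.
#' @return Array of excitation intensity in mW/mm^2 (linear scaling of the
#'   track-length fluence by the coupled power).
#' @export
scale_fluence <- function(profile, coupled_power_uW) {
  if (coupled_power_uW <= 0) stop("coupled power must be > 0", call. = FALSE)
  profile$values * (coupled_power_uW / 1000)
}

#' Area of an iso-intensity excitation contour in an axial slice
#'
#' Counts voxels in the central y-slice at or above an intensity threshold;
#' used for the 2.5 mW/mm^2 contours at different coupled powers.
#'
#' @param intensity Array from [scale_fluence()].
#' @param profile The originating `fluence_profile` (for voxel size).
#' @param level Contour level in the same units as `intensity`.
#' @return Contour area in mm^2.
#' @export
contour_area <- function(intensity, profile, level = 2.5) {
  j <- ceiling(dim(intensity)[2] / 2)
  sum(intensity[, j, ] >= level) * profile$grid$voxel_size^2
}
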