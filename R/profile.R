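#' Look up a sensitivity profile at points in fiber-local coordinates
#'
#' Evaluates a fiber's sensitivity field at arbitrary 3-D positions given the
#' fiber tip. Positions are translated into the profile's tip-centered frame
#' (all fibers share the +z axis) and the voxel field is interpolated
#' trilinearly; points outside the gridded volume return 0.
#'
#' @param profile A `fluence_profile` from [simulate_fluence()] or a
#'   `gaussian_profile` from [gaussian_profile()].
#' @param points Numeric `n x 3` matrix (or length-3 vector) of positions, mm.
#' @param tip Fiber tip position, mm (default the profile's own tip).
#' @return Numeric vector of sensitivity values (>= 0).
#' @export
profile_lookup <- function(profile, points, tip = NULL) {
  UseMethod("profile_lookup")
}

#' @export
profile_lookup.fluence_profile <- function(profile, points, tip = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(tip)) tip <- profile$tip
  # shift into the profile's frame: profile tip is at profile$tip
  local <- sweep(points, 2, as.numeric(tip) - profile$tip)
  g <- profile$grid
  .trilinear_lookup(profile$values,
                    g$dims[1], g$dims[2], g$dims[3],
                    g$origin[1], g$origin[2], g$origin[3],
                    g$voxel_size, local)
}

#' Analytic Gaussian sensitivity profile
#'
#' Closed-form stand-in for a Monte Carlo fluence profile: sensitivity decays
#' as an isotropic Gaussian of the distance to a focus just beyond the fiber
#' tip, restricted to the forward half-space. Used by the fast toy fixture
#' where full photon transport is unnecessary.
#'
#' @param sigma Falloff length scale, mm (default 0.02).
#' @param forward_offset Distance of the sensitivity focus beyond the tip
#'   along +z, mm (default 0.01).
#' @return An object of class `gaussian_profile`.
#' @export
gaussian_profile <- function(sigma = 0.02, forward_offset = 0.01) {
  stopifnot(sigma > 0)
  structure(list(sigma = sigma, forward_offset = forward_offset,
                 tip = c(0, 0, 0), wavelength = NA_real_),
            class = "gaussian_profile")
}

#' @export
profile_lookup.gaussian_profile <- function(profile, points, tip = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(tip)) tip <- profile$tip
  local <- sweep(points, 2, as.numeric(tip))
  local[, 3] <- local[, 3] - profile$forward_offset
  v <- exp(-rowSums(local^2) / (2 * profile$sigma^2))
  v[local[, 3] < -profile$forward_offset] <- 0   # dark behind the tip face
  v
}

# Peak sensitivity of a profile (anchor for brightness normalization).
profile_peak <- function(profile) {
  if (inherits(profile, "gaussian_profile")) return(1)
  max(profile$values)
}

#' Persist / restore simulation artifacts
#'
#' Containers (fluence profiles, layouts, mixing matrices, traces, results)
#' are serialized as RDS with their full metadata (grid geometry, wavelength,
#' packet count, seeds); summary tables are exported separately as CSV.
#'
#' @param x Object to persist.
#' @param path File path.
#' @return `read_artifact` returns the restored object.
#' @export
write_artifact <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) readRDS(path)
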