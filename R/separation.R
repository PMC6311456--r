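#' Inverse-filter fiber recordings to remove indicator dynamics
#'
#' Deconvolves the indicator waveform from each recorded trace:
#' `z_i = w^-1 * y_i`, turning fiber fluorescence `Y = M X` into
#' `Z = M S`, the mixing applied directly to the underlying (deconvolved)
#' activity. The exact discrete LTI inverse (back-substitution through the
#' lower-triangular Toeplitz convolution system) is used when the
#' discretized kernel is minimum phase. For non-minimum-phase kernels (the
#' framed GCaMP6f kernel has two zeros inside the unit circle) the exact
#' inverse is exponentially ill-conditioned, so the kernel is factored into
#' its minimum-phase and maximum-phase parts via its zeros and inverted
#' causally/anticausally. This recovers the deconvolved signal exactly
#' except within a geometrically decaying boundary region at the trace end
#' (reported in the `boundary_frames` attribute, about 140 frames at 20 Hz);
#' a warning notes the switch.
#'
#' @param Y A `trace_matrix` (or plain matrix) of recorded traces, one row
#'   per channel.
#' @param kernel An `indicator_kernel`; resampled internally to the frame
#'   rate of `Y` if needed.
#' @return A `trace_matrix` of deconvolved traces (role `"deconvolved"`).
#' @export
inverse_filter <- function(Y, kernel) {
  fr <- if (inherits(Y, "trace_matrix")) Y$frame_rate else 1 / kernel$dt
  Yv <- if (inherits(Y, "trace_matrix")) Y$values else as.matrix(Y)
  k <- framed_kernel_taps(kernel, fr)
  n0 <- which(abs(k) > 1e-12 * max(abs(k)))[1]
  if (is.na(n0)) stop("kernel is identically zero", call. = FALSE)
  k <- k[n0:length(k)]
  if (n0 > 1)
    Yv <- cbind(Yv[, -seq_len(n0 - 1L), drop = FALSE],
                matrix(0, nrow(Yv), n0 - 1L))
  boundary <- 0L
  if (kernel_min_phase(k)) {
    Zv <- .deconv_rows(Yv, k)
  } else {
    warning("indicator kernel is not minimum phase; ",
            "using the stable causal/anticausal inverse ",
            "(boundary artifact at the trace end)")
    dec <- deconv_twosided(Yv, k)
    Zv <- dec$S
    boundary <- dec$boundary_frames
  }
  out <- trace_matrix(Zv, fr, "deconvolved")
  attr(out, "boundary_frames") <- boundary
  out
}

# kernel taps at the trace frame rate
framed_kernel_taps <- function(kernel, frame_rate) {
  if (is.na(frame_rate) || abs(kernel$dt - 1 / frame_rate) < 1e-12)
    kernel$w
  else
    kernel_at_rate(kernel, frame_rate)$w
}

# minimum phase <=> all zeros of sum k[m+1] x^m lie outside the unit circle
kernel_min_phase <- function(k) {
  if (length(k) < 2) return(TRUE)
  all(Mod(polyroot(k)) > 1 + 1e-9)
}

# ascending complex coefficients of prod_i (1 - y / r_i)
poly_from_reciprocal_roots <- function(r) {
  c0 <- 1 + 0i
  for (ri in r) c0 <- c(c0, 0) - c(0i, c0 / ri)
  c0
}

# stable two-sided inverse for non-minimum-phase kernels: factor the kernel
# polynomial at its zeros into a minimum-phase part (zeros outside the unit
# circle, inverted causally) and a maximum-phase part (zeros inside,
# inverted anticausally on the reversed signal). Exact away from the trace
# end; the missing convolution tail injects an error decaying geometrically
# (rate = largest inside-zero modulus) into the final frames.
deconv_twosided <- function(Y, k) {
  r <- polyroot(k)
  inside <- Mod(r) < 1
  if (any(abs(Mod(r) - 1) < 1e-6))
    warning("indicator kernel has zeros near the unit circle; ",
            "deconvolution is ill-conditioned")
  pmin <- Re(poly_from_reciprocal_roots(r[!inside])) * k[1]
  pmax <- Re(poly_from_reciprocal_roots(r[inside]))
  rho <- max(Mod(r)[inside])
  boundary <- as.integer(ceiling(log(1e-9) / log(rho)))
  S1 <- .deconv_rows(Y, pmin)
  d <- length(pmax) - 1L
  T <- ncol(Y)
  Yt <- S1[, rev(seq_len(T)), drop = FALSE]
  W <- cbind(matrix(0, nrow(Y), d), Yt)[, seq_len(T), drop = FALSE]
  St <- .deconv_rows(W, rev(pmax))
  list(S = St[, rev(seq_len(T)), drop = FALSE], boundary_frames = boundary)
}

#' Re-apply the indicator waveform to separated components
#'
#' Convolves each component with the indicator kernel (causal, truncated to
#' the trace length), producing fluorescence traces corresponding to the
#' identified components.
#'
#' @param S A `trace_matrix` (or matrix) of deconvolved/separated components.
#' @param kernel An `indicator_kernel`.
#' @return A `trace_matrix` (role `"separated"`).
#' @export
refilter <- function(S, kernel) {
  fr <- if (inherits(S, "trace_matrix")) S$frame_rate else 1 / kernel$dt
  Sv <- if (inherits(S, "trace_matrix")) S$values else as.matrix(S)
  k <- framed_kernel_taps(kernel, fr)
  T <- ncol(Sv)
  out <- t(apply(Sv, 1, function(x)
    convolve(x, rev(k), type = "open")[seq_len(T)]))
  trace_matrix(out, fr, "separated")
}

#' Whiten multichannel data
#'
#' Eigendecomposition whitening: the transform is computed from the data
#' covariance about the data mean, then applied to the raw (uncentered)
#' data so that non-negative sources stay grounded at zero. The output has
#' identity covariance; rank-deficient covariances are reduced to their
#' numerical rank with a warning.
#'
#' @param Z A `trace_matrix` or matrix, channels x frames, with at least two
#'   channels and more frames than channels.
#' @param rank_tol Relative eigenvalue floor for rank detection
#'   (default 1e-10).
#' @return List with `Zw` (whitened data, possibly fewer rows), `V` (the
#'   whitening transform, `Zw = V Z`), `eigenvalues`, `rank`.
#' @export
whiten <- function(Z, rank_tol = 1e-10) {
  Zv <- if (inherits(Z, "trace_matrix")) Z$values else as.matrix(Z)
  if (nrow(Zv) < 2) stop("whitening needs at least 2 channels", call. = FALSE)
  if (ncol(Zv) <= nrow(Zv))
    stop("whitening needs more frames than channels", call. = FALSE)
  C <- stats::cov(t(Zv))
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values)
  if (!all(keep))
    warning("rank-deficient covariance: reducing ", nrow(Zv), " channels to ",
            sum(keep))
  V <- diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(e$vectors[, keep,
                                                                 drop = FALSE])
  list(Zw = V %*% Zv, V = V, eigenvalues = e$values, rank = sum(keep))
}

# objective: mean squared negative part of the rotated components
nnica_objective <- function(W, Zw) {
  y <- W %*% Zw
  sum(pmin(y, 0)^2) / ncol(Zw)
}

#' Non-negative independent component analysis
#'
#' Blind source separation under non-negativity: after whitening, finds an
#' orthonormal rotation `W` minimizing the reconstruction error between the
#' whitened data and its reconstruction from the rectified components,
#' `J(W) = mean_t || min(W z_t, 0) ||^2`. Optimization follows the geodesic
#' gradient on the rotation group: `W <- expm(-eta * A) W` with `A` the
#' antisymmetric part of the natural gradient, with backtracking line search
#' on `eta`, guaranteeing orthonormality and monotone descent.
#'
#' @param Z Data matrix or `trace_matrix`, channels x frames (typically the
#'   inverse-filtered fiber recordings).
#' @param n_components Number of components (<= channels; default all
#'   channels). Fewer components operate in the top-variance whitened
#'   subspace.
#' @param max_iter Maximum accepted rotation steps (default 1000).
#' @param tol Relative decrease of `J` treated as convergence
#'   (default 1e-8).
#' @param seed Seed for the random orthonormal initialization.
#' @param restarts Number of seeded restarts, keeping the best objective
#'   (default 1).
#' @return A `separation_result`: list with `S_est` (components x frames),
#'   `W` (rotation in whitened space), `unmixing` (`W %*% V`, applied to the
#'   raw data), `whitening`, `J` (objective per accepted iteration),
#'   `iterations`, `converged`, `seed`.
#' @export
nonneg_ica <- function(Z, n_components = NULL, max_iter = 1000, tol = 1e-8,
                       seed = 1L, restarts = 1L) {
  Zv <- if (inherits(Z, "trace_matrix")) Z$values else as.matrix(Z)
  if (!is.null(n_components) && n_components > nrow(Zv))
    stop("n_components must not exceed the number of channels",
         call. = FALSE)
  wh <- whiten(Zv)
  nc <- if (is.null(n_components)) wh$rank else min(n_components, wh$rank)
  Zw <- wh$Zw[seq_len(nc), , drop = FALSE]   # top-variance whitened dims
  V <- wh$V[seq_len(nc), , drop = FALSE]
  seeds <- split_seed(seed, max(1L, restarts))
  best <- NULL
  for (r in seq_along(seeds)) {
    fit <- nnica_fit(Zw, nc, max_iter, tol, seeds[r])
    if (is.null(best) || fit$J[length(fit$J)] < best$J[length(best$J)])
      best <- fit
  }
  structure(list(S_est = best$W %*% Zw, W = best$W,
                 unmixing = best$W %*% V,
                 whitening = V, J = best$J, iterations = best$iterations,
                 converged = best$converged, seed = as.integer(seed)),
            class = "separation_result")
}

nnica_fit <- function(Zw, nc, max_iter, tol, seed) {
  T <- ncol(Zw)
  W <- with_seed(seed, qr.Q(qr(matrix(rnorm(nc * nc), nc, nc))))
  y <- W %*% Zw
  J <- sum(pmin(y, 0)^2) / T
  J_trace <- J
  eta <- 0.5
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    G <- (2 / T) * tcrossprod(pmin(y, 0), Zw)
    A <- G %*% t(W) - W %*% t(G)
    if (max(abs(A)) < 1e-14) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:30) {
      W_try <- rotation_step(A, eta, W)
      y_try <- W_try %*% Zw
      J_try <- sum(pmin(y_try, 0)^2) / T
      if (J_try < J) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) { converged <- TRUE; break }
    W <- W_try
    y <- y_try
    rel <- (J - J_try) / max(J, .Machine$double.eps)
    J <- J_try
    J_trace <- c(J_trace, J)
    iters <- it
    eta <- min(eta * 1.5, 10)
    if (it %% 100 == 0) {
      # polar re-orthonormalization against numerical drift
      sv <- svd(W)
      W <- sv$u %*% t(sv$v)
      y <- W %*% Zw
    }
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("non-negative ICA did not converge in ", max_iter, " iterations")
  list(W = W, J = J_trace, iterations = iters, converged = converged)
}

# matrix exponential step exp(-eta * A) %*% W for antisymmetric A
rotation_step <- function(A, eta, W) {
  as.matrix(Matrix::expm(-eta * A)) %*% W
}

#' Non-negative ICA by axis-pair (Jacobi) rotations
#'
#' Reference implementation: sweeps over coordinate pairs, minimizing the
#' rectification objective over each planar rotation angle by golden-section
#' search. Slow; intended for validating the geodesic optimizer on small
#' problems.
#'
#' @inheritParams nonneg_ica
#' @param sweeps Number of full pair sweeps (default 50).
#' @return List with `W`, `J` (objective after each sweep).
#' @export
nonneg_ica_jacobi <- function(Z, sweeps = 50, seed = 1L) {
  Zv <- if (inherits(Z, "trace_matrix")) Z$values else as.matrix(Z)
  wh <- whiten(Zv)
  Zw <- wh$Zw
  nc <- nrow(Zw)
  W <- with_seed(seed, qr.Q(qr(matrix(rnorm(nc * nc), nc, nc))))
  J_trace <- nnica_objective(W, Zw)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      obj <- function(th) {
        R <- diag(nc)
        R[c(i, j), c(i, j)] <- matrix(c(cos(th), -sin(th),
                                        sin(th), cos(th)), 2, 2)
        nnica_objective(R %*% W, Zw)
      }
      opt <- stats::optimize(obj, c(-pi / 2, pi / 2))
      if (opt$objective < J_trace[length(J_trace)]) {
        R <- diag(nc)
        R[c(i, j), c(i, j)] <- matrix(c(cos(opt$minimum), -sin(opt$minimum),
                                        sin(opt$minimum), cos(opt$minimum)),
                                      2, 2)
        W <- R %*% W
      }
    }
    J_trace <- c(J_trace, nnica_objective(W, Zw))
    if (length(J_trace) > 2 &&
        abs(diff(utils::tail(J_trace, 2))) < 1e-12) break
  }
  list(W = W, J = J_trace)
}

#' End-to-end source separation of fiber recordings
#'
#' Pipeline composition: inverse-filter the indicator waveform, whiten, run
#' non-negative ICA, and re-apply the waveform to produce separated
#' fluorescence traces. The component count defaults to the number of
#' fibers (the technique extracts at most as many neural traces as fibers).
#'
#' @param Y A `trace_matrix` of fiber recordings (fibers x frames).
#' @param kernel The `indicator_kernel` used in the simulation.
#' @param n_components Number of components (default `nrow(Y)`; larger is an
#'   error).
#' @param ... Passed to [nonneg_ica()] (`max_iter`, `tol`, `seed`,
#'   `restarts`).
#' @details For non-minimum-phase kernels the deconvolution carries a
#'   boundary artifact in the final frames (see [inverse_filter()]); those
#'   frames are dropped before whitening and ICA, so the separated traces
#'   are shorter than the recording by the `frames_trimmed` element.
#' @return A `separation_result` with the additional elements `S_fluor`
#'   (the separated fluorescence `trace_matrix`) and `frames_trimmed`.
#' @export
separate_sources <- function(Y, kernel, n_components = NULL, ...) {
  Yv <- if (inherits(Y, "trace_matrix")) Y$values else as.matrix(Y)
  if (is.null(n_components)) n_components <- nrow(Yv)
  if (n_components > nrow(Yv))
    stop("cannot extract more components than fibers", call. = FALSE)
  Z <- inverse_filter(Y, kernel)
  b <- attr(Z, "boundary_frames")
  Zv <- Z$values
  if (b > 0 && ncol(Zv) > 4 * b) Zv <- Zv[, seq_len(ncol(Zv) - b),
                                          drop = FALSE]
  else b <- 0L
  res <- nonneg_ica(Zv, n_components = n_components, ...)
  res$S_fluor <- refilter(trace_matrix(res$S_est, Z$frame_rate, "separated"),
                          kernel)
  res$frames_trimmed <- b
  res
}
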