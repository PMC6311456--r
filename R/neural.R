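#' GCaMP indicator response kernel
#'
#' Unit-peak fluorescence waveform of a single spike: linear rise from 0 to
#' 1 over `[0, t_peak]`, then exponential decay with half-life `t_half`
#' (decay constant `t_half / ln 2`). Defaults are GCaMP6f
#' (`t_peak = 0.14 s`, `t_half = 0.32 s`).
#'
#' @param t_peak Time to peak, s (default 0.14).
#' @param t_half Decay half-life, s (default 0.32).
#' @param dt Sample interval, s (default 0.01); must satisfy
#'   `0 < dt <= t_peak`.
#' @param length Kernel duration, s (default `t_peak + 8 * t_half`); must
#'   exceed `t_peak`.
#' @param rise Rise shape, `"linear"` (default) or `"exponential"`
#'   (saturating rise reaching ~1 at `t_peak`).
#' @return An `indicator_kernel`: list with sample times `t`, samples `w`
#'   (unit peak), and the shape constants.
#' @export
gcamp_kernel <- function(t_peak = 0.14, t_half = 0.32, dt = 0.01,
                         length = t_peak + 8 * t_half,
                         rise = c("linear", "exponential")) {
  rise <- match.arg(rise)
  if (dt <= 0 || dt > t_peak)
    stop("dt must satisfy 0 < dt <= t_peak", call. = FALSE)
  if (length <= t_peak) stop("length must exceed t_peak", call. = FALSE)
  t <- seq(0, length, by = dt)
  tau <- t_half / log(2)
  w <- ifelse(t <= t_peak,
              if (rise == "linear") t / t_peak
              else (1 - exp(-5 * t / t_peak)) / (1 - exp(-5)),
              exp(-(t - t_peak) / tau))
  structure(list(t = t, w = w, t_peak = t_peak, t_half = t_half, dt = dt,
                 rise = rise),
            class = "indicator_kernel")
}

#' Resample an indicator kernel to a recording frame rate
#'
#' Block-means the kernel samples so that convolution at the frame rate
#' matches fine-rate convolution followed by frame averaging.
#'
#' @param kernel An `indicator_kernel`.
#' @param frame_rate Frames per second; `1/dt` must be an integer multiple.
#' @return An `indicator_kernel` sampled at `1/frame_rate`.
#' @export
kernel_at_rate <- function(kernel, frame_rate) {
  fine_rate <- 1 / kernel$dt
  factor <- fine_rate / frame_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("frame_rate must evenly divide the kernel sampling rate",
         call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(kernel)
  n <- (length(kernel$w) %/% factor) * factor
  w <- colMeans(matrix(kernel$w[seq_len(n)], nrow = factor))
  structure(list(t = seq(0, by = 1 / frame_rate, length.out = length(w)),
                 w = w, t_peak = kernel$t_peak, t_half = kernel$t_half,
                 dt = 1 / frame_rate, rise = kernel$rise),
            class = "indicator_kernel")
}

#' Simulate Bernoulli spike trains
#'
#' Independent spikes per source per time bin with probability
#' `rate * dt` (a Bernoulli process per source).
#'
#' @param n_sources Number of sources.
#' @param rate Spiking rate, Hz (default 0.4).
#' @param duration Recording duration, s.
#' @param dt Bin width, s (default 0.01); requires `rate * dt <= 1`.
#' @param seed Integer seed.
#' @return A `spike_matrix`: sparse event list with fields `src`, `bin`
#'   (1-based), `n_sources`, `n_bins`, `rate`, `duration`, `dt`, `seed`.
#'   Use [as.matrix()] for the dense binary form.
#' @export
simulate_spike_trains <- function(n_sources, rate = 0.4, duration = 600,
                                  dt = 0.01, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  p <- rate * dt
  if (p < 0 || p > 1)
    stop("rate * dt must lie in [0, 1]", call. = FALSE)
  n_bins <- as.integer(round(duration / dt))
  ev <- with_seed(seed, {
    counts <- rbinom(n_sources, n_bins, p)
    src <- rep.int(seq_len(n_sources), counts)
    bin <- unlist(lapply(counts, function(k)
      if (k > 0) sort(sample.int(n_bins, k)) else integer(0)))
    list(src = src, bin = as.integer(bin))
  })
  structure(list(src = ev$src, bin = ev$bin, n_sources = as.integer(n_sources),
                 n_bins = n_bins, rate = rate, duration = duration, dt = dt,
                 seed = as.integer(seed)),
            class = "spike_matrix")
}

#' @export
as.matrix.spike_matrix <- function(x, ...) {
  m <- matrix(0L, x$n_sources, x$n_bins)
  m[cbind(x$src, x$bin)] <- 1L
  m
}

#' Fluorescence trace container
#'
#' @param values Numeric matrix, one row per source or fiber, one column per
#'   frame.
#' @param frame_rate Frames per second.
#' @param role One of `"neural"`, `"fiber"`, `"deconvolved"`, `"separated"`.
#' @return A `trace_matrix`.
#' @export
trace_matrix <- function(values, frame_rate,
                         role = c("neural", "fiber", "deconvolved",
                                  "separated")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)))
  structure(list(values = values, frame_rate = frame_rate, role = role),
            class = "trace_matrix")
}

#' Convolve spikes with the indicator kernel and downsample to frames
#'
#' Causal convolution at the spike bin rate (100 Hz by default) followed by
#' block-mean downsampling to the recording frame rate.
#'
#' @param spikes A `spike_matrix`.
#' @param kernel An `indicator_kernel` sampled at the spike bin width.
#' @param frame_rate Frames per second; must evenly divide `1/dt`.
#' @return A `trace_matrix` of true neural fluorescence (role `"neural"`).
#' @export
convolve_and_frame <- function(spikes, kernel, frame_rate = 20) {
  stopifnot(inherits(spikes, "spike_matrix"),
            inherits(kernel, "indicator_kernel"))
  if (abs(kernel$dt - spikes$dt) > 1e-12)
    stop("kernel must be sampled at the spike bin width", call. = FALSE)
  fine_rate <- 1 / spikes$dt
  factor <- fine_rate / frame_rate
  if (frame_rate > fine_rate || abs(factor - round(factor)) > 1e-9)
    stop("frame_rate must evenly divide the simulation rate", call. = FALSE)
  factor <- as.integer(round(factor))
  n_bins <- (spikes$n_bins %/% factor) * factor
  keep <- spikes$bin <= n_bins
  vals <- .spikes_to_frames(spikes$src[keep], spikes$bin[keep],
                            spikes$n_sources, n_bins, kernel$w, factor)
  trace_matrix(vals, frame_rate, "neural")
}

#' Mix neural traces through the interface
#'
#' Fiber recordings `Y = M %*% X`: each fiber collects the weighted sum of
#' the neural fluorescence traces given by its mixing-matrix row.
#'
#' @param M A `mixing_matrix` or plain fibers x sources matrix.
#' @param X A `trace_matrix` (sources x frames) or plain matrix.
#' @return A `trace_matrix` of fiber signals (role `"fiber"`).
#' @export
mix_traces <- function(M, X) {
  if (inherits(M, "mixing_matrix")) M <- M$M
  fr <- if (inherits(X, "trace_matrix")) X$frame_rate else NA_real_
  Xv <- if (inherits(X, "trace_matrix")) X$values else as.matrix(X)
  if (ncol(M) != nrow(Xv))
    stop("column count of M must equal the number of source traces",
         call. = FALSE)
  trace_matrix(M %*% Xv, fr, "fiber")
}

#' Export traces as CSV
#'
#' @param X A `trace_matrix`.
#' @param path Output file.
#' @return The path, invisibly. Columns: `time` plus one column per trace.
#' @export
write_traces_csv <- function(X, path) {
  stopifnot(inherits(X, "trace_matrix"))
  tt <- seq(0, by = 1 / X$frame_rate, length.out = ncol(X$values))
  df <- data.frame(time = tt, t(X$values))
  names(df) <- c("time", paste0("trace_", seq_len(nrow(X$values))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
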