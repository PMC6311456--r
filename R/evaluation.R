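#' Match separated traces to ground-truth neural traces by correlation
#'
#' For each separated (or raw fiber) trace, finds the simulated neural
#' fluorescence trace with the highest squared Pearson correlation. A trace
#' is an accurate match when its best r-squared reaches the threshold; each
#' extracted trace is accounted for independently (two traces may match the
#' same neuron). Zero-variance traces get r-squared 0 with a warning.
#'
#' @param S_fluor `trace_matrix` (or matrix) of extracted traces.
#' @param X_true `trace_matrix` (or matrix) of true neural fluorescence, one
#'   row per simulated (above-floor) neuron, same frame count.
#' @param r2_threshold Match threshold on r-squared (default 0.6).
#' @return A `match_result`: data frame (`trace`, `best_true`, `r2`,
#'   `matched`) with attributes `accuracy` (percent of extracted traces
#'   matched) and `r2_threshold`.
#' @export
match_components <- function(S_fluor, X_true, r2_threshold = 0.6) {
  S <- if (inherits(S_fluor, "trace_matrix")) S_fluor$values else
    as.matrix(S_fluor)
  X <- if (inherits(X_true, "trace_matrix")) X_true$values else
    as.matrix(X_true)
  if (ncol(S) != ncol(X)) stop("frame counts differ", call. = FALSE)
  best <- best_r2(S, X)
  matched <- best$r2 >= r2_threshold
  out <- data.frame(trace = seq_len(nrow(S)), best_true = best$idx,
                    r2 = best$r2, matched = matched)
  attr(out, "accuracy") <- 100 * mean(matched)
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("match_result", "data.frame")
  out
}

# best squared Pearson correlation of each row of S against rows of X,
# processed in column chunks of X to bound memory
best_r2 <- function(S, X, chunk = 4000L) {
  T <- ncol(S)
  Sc <- S - rowMeans(S)
  s_sd <- sqrt(rowSums(Sc^2))
  if (any(s_sd == 0)) warning("zero-variance extracted trace; r2 set to 0")
  best_val <- rep(0, nrow(S))
  best_idx <- rep(NA_integer_, nrow(S))
  for (start in seq(1, nrow(X), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    Xc <- X[idx, , drop = FALSE]
    Xc <- Xc - rowMeans(Xc)
    x_sd <- sqrt(rowSums(Xc^2))
    num <- Sc %*% t(Xc)
    den <- outer(s_sd, x_sd)
    r2 <- (num / den)^2
    r2[!is.finite(r2)] <- 0
    mx <- apply(r2, 1, max)
    wx <- apply(r2, 1, which.max)
    upd <- mx > best_val | is.na(best_idx)
    best_val[upd] <- mx[upd]
    best_idx[upd] <- idx[wx[upd]]
  }
  list(r2 = best_val, idx = best_idx)
}

#' Matching accuracy of raw fiber recordings
#'
#' Applies the same correlation matching to the raw fiber traces without
#' any source separation; the without-separation baseline.
#'
#' @inheritParams match_components
#' @param Y `trace_matrix` of raw fiber recordings.
#' @return A `match_result` (see [match_components()]).
#' @export
raw_fiber_accuracy <- function(Y, X_true, r2_threshold = 0.6) {
  match_components(Y, X_true, r2_threshold)
}

#' Paired t-test on the separation improvement
#'
#' Two-sided paired t-test of per-iteration matching accuracy with
#' separation against the raw-fiber baseline.
#'
#' @param separated Numeric vector of per-iteration accuracies (percent)
#'   with separation.
#' @param raw Matching accuracies without separation, same length (>= 2).
#' @return List with `t`, `p_value`, `df`, `mean_improvement`.
#' @export
paired_improvement_test <- function(separated, raw) {
  stopifnot(length(separated) == length(raw), length(raw) >= 2)
  d <- separated - raw
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p_value = 1,
                                  df = length(d) - 1, mean_improvement = 0))
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = length(d) - 1,
                mean_improvement = mean(d)))
  }
  tt <- t.test(separated, raw, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_improvement = mean(d))
}

# upward crossings of a level: frames t with x[t] >= level, x[t-1] < level
upward_crossings <- function(x, level) {
  which(x[-1] >= level & x[-length(x)] < level) + 1L
}

#' Threshold-crossing spike-detection ROC
#'
#' Ground-truth events are upward crossings of `event_threshold` on the true
#' trace; detections are upward crossings of a swept threshold on the
#' extracted trace. A detection within `tolerance_frames` of a true event is
#' a true positive; each event counts as detected at most once. Both classes
#' are counted in tolerance-window units: the true positive rate is the
#' fraction of events detected, and the false positive rate is the number of
#' detections outside all event windows divided by the number of
#' tolerance-sized windows that fit in the event-free portion of the trace
#' (so a detector firing at random positions tracks the diagonal). The curve
#' is completed with (0,0) and (1,1) and the AUC computed by trapezoid.
#'
#' @param separated_trace Numeric vector, the extracted trace.
#' @param true_trace Numeric vector, the matched ground-truth fluorescence,
#'   same length and frame rate.
#' @param event_threshold Level defining ground-truth events. Default: half
#'   the framed single-spike peak (set by the caller; see
#'   [default_event_threshold()]).
#' @param tolerance_frames Pairing window, frames (default 2).
#' @param n_sweep Number of detection thresholds swept (default 50).
#' @return A `roc_result`: list with `roc` (data frame `threshold`, `tpr`,
#'   `fpr`), `auc`, `n_events`.
#' @export
spike_detection_roc <- function(separated_trace, true_trace,
                                event_threshold, tolerance_frames = 2L,
                                n_sweep = 50L) {
  stopifnot(length(separated_trace) == length(true_trace))
  events <- upward_crossings(true_trace, event_threshold)
  if (!length(events))
    stop("true trace has no threshold-crossing events", call. = FALSE)
  T <- length(true_trace)
  near_event <- rep(FALSE, T)
  for (e in events)
    near_event[max(1, e - tolerance_frames):min(T, e + tolerance_frames)] <-
      TRUE
  # negatives in tolerance-window units so random detections are unbiased
  n_neg <- max(1, floor(sum(!near_event) / (2 * tolerance_frames + 1)))
  lv <- quantile(separated_trace, probs = seq(0.02, 0.98,
                                              length.out = n_sweep),
                 names = FALSE)
  lv <- unique(sort(lv, decreasing = TRUE))
  pts <- vapply(lv, function(th) {
    det <- upward_crossings(separated_trace, th)
    if (!length(det)) return(c(0, 0))
    hit <- vapply(events, function(e)
      any(abs(det - e) <= tolerance_frames), logical(1))
    fp <- sum(!near_event[det])
    c(sum(hit) / length(events), min(1, fp / n_neg))
  }, numeric(2))
  roc <- data.frame(threshold = lv, tpr = pts[1, ], fpr = pts[2, ])
  # trapezoid over the empirical points as-is: monotonizing a noisy sweep
  # (e.g. by a running maximum) would bias a chance-level curve upward
  ord <- order(roc$fpr, roc$tpr)
  fpr <- c(0, roc$fpr[ord], 1)
  tpr <- c(0, roc$tpr[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, n_events = length(events),
                 event_threshold = event_threshold,
                 tolerance_frames = tolerance_frames),
            class = "roc_result")
}

#' Default spike-detection event threshold
#'
#' Half the peak amplitude of a single framed spike: the indicator kernel
#' convolved with one spike and block-averaged to the frame rate.
#'
#' @param kernel An `indicator_kernel`.
#' @param frame_rate Recording frame rate, Hz.
#' @return Scalar threshold in trace units.
#' @export
default_event_threshold <- function(kernel, frame_rate) {
  0.5 * max(kernel_at_rate(kernel, frame_rate)$w)
}

# correlation matching against Bernoulli-kernel sources regenerated from
# sparse spikes in chunks, without holding the full trace matrix in memory
match_spikes_chunked <- function(S, spikes, kernel, frame_rate,
                                 r2_threshold = 0.6, chunk = 2000L) {
  n_src <- spikes$n_sources
  Sc <- S - rowMeans(S)
  s_sd <- sqrt(rowSums(Sc^2))
  if (any(s_sd == 0)) warning("zero-variance extracted trace; r2 set to 0")
  best_val <- rep(0, nrow(S))
  best_idx <- rep(1L, nrow(S))
  for (start in seq(1, n_src, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_src)
    Xch <- frame_subset(spikes, idx, kernel, frame_rate)[, seq_len(ncol(S)),
                                                         drop = FALSE]
    Xc <- Xch - rowMeans(Xch)
    x_sd <- sqrt(rowSums(Xc^2))
    r2 <- (Sc %*% t(Xc) / outer(s_sd, x_sd))^2
    r2[!is.finite(r2)] <- 0
    mx <- apply(r2, 1, max)
    wx <- apply(r2, 1, which.max)
    upd <- mx > best_val
    best_val[upd] <- mx[upd]
    best_idx[upd] <- idx[wx[upd]]
  }
  matched <- best_val >= r2_threshold
  out <- data.frame(trace = seq_len(nrow(S)), best_true = best_idx,
                    r2 = best_val, matched = matched)
  attr(out, "accuracy") <- 100 * mean(matched)
  attr(out, "r2_threshold") <- r2_threshold
  class(out) <- c("match_result", "data.frame")
  out
}

#' Random-trace negative control
#'
#' Regenerates an independent set of Bernoulli-kernel fluorescence traces
#' with the same rate and duration and evaluates the extracted traces
#' against them two ways: correlation matching against the whole control
#' pool (expected ~0% accurate at the default threshold), and
#' spike-detection AUC of each extracted trace against an unrelated random
#' trace paired one-to-one (expected ~0.5; no best-match selection enters
#' the AUC, mirroring how the detection analysis is run on matched true
#' traces).
#'
#' @param S_fluor `trace_matrix` of extracted traces.
#' @param rate Spike rate of the control traces, Hz.
#' @param kernel The `indicator_kernel`.
#' @param frame_rate Frame rate of `S_fluor`, Hz.
#' @param n_control Number of control traces (default: number of extracted
#'   traces).
#' @param r2_threshold Match threshold (default 0.6).
#' @param event_threshold ROC event level (default
#'   [default_event_threshold()]).
#' @param tolerance_frames ROC pairing window (default 2).
#' @param seed Seed for the control generator.
#' @return List with `match` (a `match_result`), `auc` (per extracted
#'   trace), `mean_auc`, `control_seed`.
#' @export
random_control <- function(S_fluor, rate, kernel, frame_rate,
                           n_control = NULL, r2_threshold = 0.6,
                           event_threshold = NULL, tolerance_frames = 2L,
                           seed = 1L) {
  S <- if (inherits(S_fluor, "trace_matrix")) S_fluor$values else
    as.matrix(S_fluor)
  if (is.null(n_control)) n_control <- nrow(S)
  duration <- ceiling(ncol(S) / frame_rate)
  spikes <- simulate_spike_trains(n_control, rate, duration,
                                  dt = kernel$dt, seed = seed)
  m <- match_spikes_chunked(S, spikes, kernel, frame_rate, r2_threshold)
  if (is.null(event_threshold))
    event_threshold <- default_event_threshold(kernel, frame_rate)
  pair <- ((seq_len(nrow(S)) - 1L) %% n_control) + 1L
  Xref <- frame_subset(spikes, sort(unique(pair)), kernel, frame_rate)
  auc <- vapply(seq_len(nrow(S)), function(i) {
    ref <- Xref[match(pair[i], sort(unique(pair))), seq_len(ncol(S))]
    if (!length(upward_crossings(ref, event_threshold))) return(NA_real_)
    spike_detection_roc(S[i, ], ref, event_threshold, tolerance_frames)$auc
  }, numeric(1))
  list(match = m, auc = auc, mean_auc = mean(auc, na.rm = TRUE),
       control_seed = as.integer(seed))
}

#' Sweep the r-squared matching threshold
#'
#' Reports, for each matching threshold, the number of matched traces and
#' their mean spike-detection AUC against the matched true traces. More
#' permissive thresholds match more traces at the price of lower detection
#' accuracy.
#'
#' @param match A `match_result` from [match_components()].
#' @param S_fluor The extracted traces evaluated in `match`.
#' @param X_true The true traces evaluated in `match`.
#' @param r2_thresholds Thresholds to sweep (default
#'   `c(0.2, 0.4, 0.6, 0.8)`).
#' @param event_threshold,tolerance_frames Passed to
#'   [spike_detection_roc()].
#' @return Data frame with columns `r2_threshold`, `n_matched`, `mean_auc`.
#' @export
threshold_sweep_roc <- function(match, S_fluor, X_true,
                                r2_thresholds = c(0.2, 0.4, 0.6, 0.8),
                                event_threshold, tolerance_frames = 2L) {
  S <- if (inherits(S_fluor, "trace_matrix")) S_fluor$values else
    as.matrix(S_fluor)
  X <- if (inherits(X_true, "trace_matrix")) X_true$values else
    as.matrix(X_true)
  auc_all <- vapply(seq_len(nrow(S)), function(i) {
    ref <- X[match$best_true[i], ]
    if (!length(upward_crossings(ref, event_threshold))) return(NA_real_)
    spike_detection_roc(S[i, ], ref, event_threshold, tolerance_frames)$auc
  }, numeric(1))
  out <- lapply(sort(r2_thresholds), function(th) {
    sel <- match$r2 >= th
    data.frame(r2_threshold = th, n_matched = sum(sel),
               mean_auc = if (any(sel)) mean(auc_all[sel], na.rm = TRUE)
                          else NA_real_)
  })
  do.call(rbind, out)
}
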