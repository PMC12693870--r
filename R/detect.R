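#' First derivative by finite differences
#'
#' Forward difference at the first sample, backward at the last, central
#' differences everywhere else; exact for linear signals at every index.
#' One linear pass, output on the same grid as the input.
#'
#' @param trace A [signal_trace()] of length >= 3.
#' @return A [derivative_trace()].
#' @export
compute_derivative <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- trace$samples
  n <- length(s)
  if (n < 3L) stop("trace too short: derivative needs at least 3 samples")
  d <- numeric(n)
  d[1L] <- (s[2L] - s[1L]) * trace$fs
  d[n] <- (s[n] - s[n - 1L]) * trace$fs
  d[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) * trace$fs / 2
  derivative_trace(d, trace$fs, trace$t_start)
}

#' Robust automatic derivative threshold
#'
#' theta = k * MAD(s') / 0.6745, i.e. k times the normal-consistent median
#' absolute deviation of the derivative — a noise-scale estimate that sparse
#' large events barely inflate.
#'
#' @param deriv A [derivative_trace()].
#' @param k Positive multiplier (default 5).
#' @return Threshold theta in V/s. A zero threshold (all-zero derivative) is
#'   returned flagged with attribute `degenerate = TRUE`; detection refuses to
#'   run with it.
#' @export
auto_threshold <- function(deriv, k = 5) {
  stopifnot(inherits(deriv, "derivative_trace"), k > 0)
  theta <- k * stats::mad(deriv$values)
  if (theta <= 0) attr(theta, "degenerate") <- TRUE
  theta
}

# maximal runs of |v| > theta, split at internal sign changes, as a data.frame
# (start, end, sign); runs shorter than min_len dropped
threshold_runs <- function(v, theta, min_len) {
  m <- .runs_cpp(v, theta, as.integer(min_len))
  data.frame(start = m[, 1L], end = m[, 2L], sign = m[, 3L])
}

empty_events <- function() {
  data.frame(event_id = integer(), t_pos_s = numeric(), t_neg_s = numeric(),
             v_pos_V = numeric(), v_neg_V = numeric(), dV_V = numeric(),
             dt_s = numeric(), left_zc_s = numeric(), right_zc_s = numeric(),
             left_idx = integer(), pos_idx = integer(), neg_idx = integer(),
             right_idx = integer())
}

#' Detect bipolar events from a derivative trace
#'
#' Single linear pass: (i) find maximal supra-threshold runs of |s'| carrying
#' the local slope sign; (ii) group a positive-slope lobe with the following
#' negative-slope lobe (optionally absorbing a trailing positive lobe) within
#' `max_gap_s`; (iii) locate the raw positive peak at the s' zero crossing
#' between the paired lobes and the negative peak at the crossing after the
#' negative lobe; (iv) merge events closer than `refractory_s`, keeping the
#' larger peak-to-peak amplitude. Events touching the trace edges are dropped.
#'
#' @param deriv A [derivative_trace()].
#' @param raw The raw [signal_trace()] on the same grid.
#' @param cfg A [detector_config()].
#' @param theta Resolved threshold (V/s); defaults to `cfg$threshold_V_s` or
#'   the auto threshold.
#' @return data.frame of detected events (`event_id`, `t_pos_s`, `t_neg_s`,
#'   `v_pos_V`, `v_neg_V`, `dV_V`, `dt_s`, `left_zc_s`, `right_zc_s` plus
#'   index columns), sorted by time, with attributes `theta`,
#'   `n_edge_dropped`, `n_merged`, `n_polarity_rejected`.
#' @export
detect_events <- function(deriv, raw, cfg = detector_config(), theta = NULL) {
  stopifnot(inherits(deriv, "derivative_trace"), inherits(raw, "signal_trace"))
  if (length(deriv$values) != length(raw$samples))
    stop("derivative and raw trace must share one grid")
  if (is.null(theta)) {
    theta <- if (!is.null(cfg$threshold_V_s)) cfg$threshold_V_s
             else auto_threshold(deriv, cfg$auto_k)
  }
  if (isTRUE(attr(theta, "degenerate")) || theta <= 0)
    stop("degenerate threshold (theta <= 0): detection refuses to run")
  v <- deriv$values
  s <- raw$samples
  if (cfg$polarity == "negative-first") { v <- -v; s <- -s }
  n <- length(v)
  fs <- deriv$fs
  gap_n <- max(1L, round(cfg$max_gap_s * fs))

  runs <- .runs_cpp(v, theta, cfg$min_lobe_samples)
  m <- .group_bipolar_cpp(v, s, runs, gap_n)
  edge_dropped <- attr(m, "edge_dropped")

  if (!nrow(m)) {
    ev <- empty_events()
  } else {
    raw_v <- raw$samples                 # report in original polarity
    if (cfg$polarity == "negative-first") {
      # detection ran on -s: the first landmark is the raw minimum, the
      # second the raw maximum; swap so pos_idx always names the raw maximum
      ev <- data.frame(left_idx = m[, 1L], pos_idx = m[, 3L],
                       neg_idx = m[, 2L], right_idx = m[, 4L])
    } else {
      ev <- data.frame(left_idx = m[, 1L], pos_idx = m[, 2L],
                       neg_idx = m[, 3L], right_idx = m[, 4L])
    }
    ev$v_pos_V <- raw_v[ev$pos_idx]
    ev$v_neg_V <- raw_v[ev$neg_idx]
  }

  n_pol <- 0L
  if (nrow(ev)) {
    keep <- ev$v_pos_V > ev$v_neg_V
    n_pol <- sum(!keep)
    ev <- ev[keep, , drop = FALSE]
  }

  # refractory merge on event centres, keep larger |v_pos - v_neg|
  n_merged <- 0L
  if (nrow(ev) > 1L && cfg$refractory_s > 0) {
    centre <- (ev$pos_idx + ev$neg_idx) / 2 / fs
    keep <- rep(TRUE, nrow(ev))
    amp <- ev$v_pos_V - ev$v_neg_V
    last <- 1L
    for (k in 2L:nrow(ev)) {
      if (centre[k] - centre[last] < cfg$refractory_s) {
        n_merged <- n_merged + 1L
        if (amp[k] > amp[last]) { keep[last] <- FALSE; last <- k }
        else keep[k] <- FALSE
      } else last <- k
    }
    ev <- ev[keep, , drop = FALSE]
  }

  if (nrow(ev)) {
    t0 <- raw$t_start
    ev <- data.frame(event_id = seq_len(nrow(ev)),
                     t_pos_s = idx_to_time(ev$pos_idx, fs, t0),
                     t_neg_s = idx_to_time(ev$neg_idx, fs, t0),
                     v_pos_V = ev$v_pos_V, v_neg_V = ev$v_neg_V,
                     dV_V = ev$v_pos_V - ev$v_neg_V,
                     dt_s = abs(ev$neg_idx - ev$pos_idx) / fs,
                     left_zc_s = idx_to_time(ev$left_idx, fs, t0),
                     right_zc_s = idx_to_time(ev$right_idx, fs, t0),
                     left_idx = ev$left_idx, pos_idx = ev$pos_idx,
                     neg_idx = ev$neg_idx, right_idx = ev$right_idx)
  } else ev <- empty_events()
  attr(ev, "theta") <- as.numeric(theta)
  attr(ev, "n_edge_dropped") <- edge_dropped
  attr(ev, "n_merged") <- n_merged
  attr(ev, "n_polarity_rejected") <- n_pol
  ev
}

#' Full derivative pipeline: differentiate, threshold, detect, extract
#'
#' Composes [compute_derivative()], threshold resolution, [detect_events()]
#' and feature extraction in at most three linear passes over the trace.
#'
#' @param trace A [signal_trace()].
#' @param cfg A [detector_config()].
#' @param theta Optional pre-resolved threshold (V/s).
#' @return Detected-event data.frame (see [detect_events()]); features `dV_V`
#'   and `dt_s` are included per event.
#' @export
run_pipeline <- function(trace, cfg = detector_config(), theta = NULL) {
  deriv <- compute_derivative(trace)
  detect_events(deriv, trace, cfg, theta)
}

#' Event centre times of a detection table
#'
#' @param events Detected-event data.frame.
#' @return Numeric vector `(t_pos_s + t_neg_s) / 2`.
#' @export
event_centers <- function(events) (events$t_pos_s + events$t_neg_s) / 2
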