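#' Multi-stage amplitude-thresholding reference detector
#'
#' The classical comparator pipeline: (1) estimate the baseline with a moving
#' median and subtract it; (2) mark runs where the detrended signal exceeds
#' +theta or falls below -theta; (3) pair each positive run with the nearest
#' following negative run within `pair_gap_s`. Peaks are the extremum sample
#' of each run. Emits the same event schema as the derivative detector so the
#' evaluation module treats both symmetrically.
#'
#' @param trace A [signal_trace()].
#' @param cfg A [baseline_config()].
#' @param theta Resolved amplitude threshold (V); defaults to
#'   `cfg$amp_threshold_V` or `cfg$auto_k` times the MAD noise scale of the
#'   detrended signal.
#' @return Detected-event data.frame (same columns as [detect_events()]),
#'   with attribute `theta`.
#' @export
baseline_detect <- function(trace, cfg = baseline_config(), theta = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- trace$samples
  n <- length(s)
  fs <- trace$fs
  if (cfg$detrend) {
    k <- round(cfg$baseline_window_s * fs)
    if (k %% 2 == 0) k <- k + 1L
    if (k >= n) stop("baseline window longer than trace")
    x <- s - stats::runmed(s, k, endrule = "constant")
  } else {
    x <- s - stats::median(s)
  }
  if (is.null(theta)) {
    theta <- if (!is.null(cfg$amp_threshold_V)) cfg$amp_threshold_V
             else cfg$auto_k * stats::mad(x)
  }
  if (theta <= 0) stop("degenerate amplitude threshold (theta <= 0)")
  gap_n <- max(1L, round(cfg$pair_gap_s * fs))

  runs <- .runs_cpp(x, theta, cfg$min_event_samples)
  m <- .pair_runs_cpp(x, runs, gap_n)

  if (!nrow(m)) {
    ev <- empty_events()
  } else {
    t0 <- trace$t_start
    ev <- data.frame(event_id = seq_len(nrow(m)),
                     t_pos_s = idx_to_time(m[, 2L], fs, t0),
                     t_neg_s = idx_to_time(m[, 3L], fs, t0),
                     v_pos_V = s[m[, 2L]], v_neg_V = s[m[, 3L]],
                     dV_V = x[m[, 2L]] - x[m[, 3L]],
                     dt_s = (m[, 3L] - m[, 2L]) / fs,
                     left_zc_s = idx_to_time(m[, 1L], fs, t0),
                     right_zc_s = idx_to_time(m[, 4L], fs, t0),
                     left_idx = m[, 1L], pos_idx = m[, 2L],
                     neg_idx = m[, 3L], right_idx = m[, 4L])
  }
  attr(ev, "theta") <- as.numeric(theta)
  ev
}

#' Tune a detector threshold to balance precision and recall
#'
#' Grid-searches the method's threshold on a ground-truthed stream and
#' returns the value minimizing |precision - recall|, breaking ties by larger
#' F1 and then by smaller threshold. The default grid is 30 log-spaced points
#' spanning 0.5-20 times the method's robust noise scale, identical in shape
#' for both methods.
#'
#' @param method `"derivative"` or `"baseline"`.
#' @param stream A `pulse_stream` with ground truth.
#' @param grid Optional numeric vector of absolute thresholds.
#' @param cfg Detector config for the chosen method ([detector_config()] or
#'   [baseline_config()]).
#' @param tol_s Matching tolerance passed to [match_events()]; default
#'   delta/2 for the stream's kinematics.
#' @param refine_steps Bisection refinements between the two grid points
#'   bracketing the precision/recall crossing (default 8; 0 disables).
#' @return List with `threshold` (chosen value) and `table` (per-threshold
#'   precision/recall/F1, refinement points appended).
#' @export
tune_balanced_threshold <- function(method = c("derivative", "baseline"),
                                    stream, grid = NULL, cfg = NULL,
                                    tol_s = NULL, refine_steps = 8L) {
  method <- match.arg(method)
  stopifnot(inherits(stream, "pulse_stream"))
  if (is.null(tol_s)) tol_s <- stream$kinematics$delta_s / 2
  if (method == "derivative") {
    if (is.null(cfg)) cfg <- detector_config_for(stream$config)
    deriv <- compute_derivative(stream$trace)
    scale <- stats::mad(deriv$values)
    detect_fun <- function(th) detect_events(deriv, stream$trace, cfg, th)
  } else {
    if (is.null(cfg)) cfg <- baseline_config_for(stream$config)
    scale <- {
      k <- round(cfg$baseline_window_s * stream$trace$fs)
      if (k %% 2 == 0) k <- k + 1L
      x <- stream$trace$samples - stats::runmed(stream$trace$samples, k,
                                                endrule = "constant")
      stats::mad(x)
    }
    detect_fun <- function(th) baseline_detect(stream$trace, cfg, th)
  }
  if (is.null(grid)) {
    if (scale <= 0) stop("cannot build tuning grid from a zero noise scale")
    grid <- exp(seq(log(0.5), log(20), length.out = 30)) * scale
  }
  if (!length(grid)) stop("empty tuning grid")
  eval_th <- function(th) {
    m <- tryCatch({
      ev <- detect_fun(th)
      mt <- match_events(ev, stream$truth, match_config(tol_s = tol_s))
      compute_metrics(mt)
    }, error = function(e) NULL)
    if (is.null(m)) return(data.frame(threshold = th, precision = NA,
                                      recall = NA, f1 = NA))
    data.frame(threshold = th, precision = m$precision, recall = m$recall,
               f1 = m$f1)
  }
  tab <- do.call(rbind, lapply(grid, eval_th))
  ok <- !is.na(tab$precision) & !is.na(tab$recall)
  if (!any(ok)) stop("tuning failed at every grid point")
  # the P - R crossing is steep in theta, so refine by bisection between the
  # neighbouring grid points where the sign of (P - R) flips
  cand <- tab[ok, , drop = FALSE]
  sgn <- sign(cand$precision - cand$recall)
  flip <- which(diff(sgn) != 0)
  if (length(flip) && refine_steps > 0) {
    i <- flip[1L]
    lo <- cand$threshold[i]; hi <- cand$threshold[i + 1L]
    for (r in seq_len(refine_steps)) {
      mid <- sqrt(lo * hi)
      row <- eval_th(mid)
      tab <- rbind(tab, row)
      if (is.na(row$precision) || is.na(row$recall)) break
      if (sign(row$precision - row$recall) == sgn[i]) lo <- mid else hi <- mid
    }
  }
  ok <- !is.na(tab$precision) & !is.na(tab$recall)
  cand <- tab[ok, , drop = FALSE]
  gap <- abs(cand$precision - cand$recall)
  best <- which(gap == min(gap))
  if (length(best) > 1L) {
    f1 <- cand$f1[best]
    best <- best[f1 == max(f1, na.rm = TRUE)]
  }
  best <- best[1L]
  list(threshold = cand$threshold[best], table = tab)
}
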