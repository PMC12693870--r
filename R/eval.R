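#' Matching configuration
#'
#' @param tol_s Fixed temporal tolerance tau for matching detections to
#'   ground truth (s).
#' @param match_on Timestamp anchoring the match: `"center"` (default,
#'   midpoint of the two peaks) or `"pos_peak"`.
#' @return List of class `match_config`.
#' @export
match_config <- function(tol_s, match_on = c("center", "pos_peak")) {
  if (tol_s <= 0) stop("tol_s must be > 0")
  structure(list(tol_s = tol_s, match_on = match.arg(match_on)),
            class = "match_config")
}

#' Match detections to ground truth within a fixed temporal tolerance
#'
#' Greedy one-to-one matching: candidate (detection, truth) pairs within
#' `tol_s` are assigned in order of increasing time distance; each truth
#' event takes at most one detection and vice versa. Surplus detections of an
#' already-matched truth event count as false positives.
#'
#' @param detected Detected-event data.frame.
#' @param truth `true_events` data.frame.
#' @param cfg A [match_config()].
#' @return List of class `match_result`: `pairs` (data.frame with `det_idx`,
#'   `truth_idx`, `dist_s` and the paired columns needed for error metrics),
#'   `unmatched_det` (row indices), `unmatched_truth` (row indices), plus
#'   `n_det`, `n_truth`.
#' @export
match_events <- function(detected, truth, cfg) {
  stopifnot(inherits(cfg, "match_config"))
  nd <- nrow(detected); nt <- nrow(truth)
  t_det <- if (nd) {
    if (cfg$match_on == "center") event_centers(detected) else detected$t_pos_s
  } else numeric(0)
  t_tru <- if (nt) {
    if (cfg$match_on == "center") truth$t0_s else truth$t_pos_s
  } else numeric(0)

  cand_d <- integer(0); cand_t <- integer(0); cand_dist <- numeric(0)
  if (nd && nt) {
    ord_t <- order(t_tru)
    tt <- t_tru[ord_t]
    for (i in seq_len(nd)) {
      lo <- findInterval(t_det[i] - cfg$tol_s, tt) + 1L
      hi <- findInterval(t_det[i] + cfg$tol_s, tt)
      if (lo <= hi) {
        js <- ord_t[lo:hi]
        cand_d <- c(cand_d, rep.int(i, length(js)))
        cand_t <- c(cand_t, js)
        cand_dist <- c(cand_dist, abs(t_det[i] - t_tru[js]))
      }
    }
  }
  pairs <- data.frame(det_idx = integer(), truth_idx = integer(),
                      dist_s = numeric())
  if (length(cand_d)) {
    ord <- order(cand_dist, cand_d, cand_t)   # deterministic tie-break
    used_d <- logical(nd); used_t <- logical(nt)
    keep <- logical(length(ord))
    for (k in ord) {
      if (!used_d[cand_d[k]] && !used_t[cand_t[k]]) {
        used_d[cand_d[k]] <- TRUE; used_t[cand_t[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    pairs <- data.frame(det_idx = cand_d[keep], truth_idx = cand_t[keep],
                        dist_s = cand_dist[keep])
    pairs <- pairs[order(pairs$det_idx), , drop = FALSE]
  }
  structure(list(pairs = pairs,
                 unmatched_det = setdiff(seq_len(nd), pairs$det_idx),
                 unmatched_truth = setdiff(seq_len(nt), pairs$truth_idx),
                 n_det = nd, n_truth = nt,
                 detected = detected, truth = truth),
            class = "match_result")
}

#' Detection metrics from a match result
#'
#' Counts and ratios: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean, FDR = 1 - precision. Over matched pairs only, the mean
#' relative peak-position error (average of the positive- and negative-peak
#' time errors, as a percentage of the true transit time) and the mean
#' relative peak-to-peak amplitude error (%). Empty denominators yield NaN
#' with an `undefined` flag, never a silent zero.
#'
#' @param match A `match_result` from [match_events()].
#' @return One-row data.frame of class `detection_metrics` with columns `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`, `fdr`, `peak_pos_err_pct`,
#'   `p2p_err_pct` and attribute `undefined` naming any NaN ratios.
#' @export
compute_metrics <- function(match) {
  stopifnot(inherits(match, "match_result"))
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_det)
  fn <- length(match$unmatched_truth)
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NaN }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NaN }
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0) 2 * precision * recall / (precision + recall)
        else { undefined <- c(undefined, "f1"); NaN }
  fdr <- if (is.finite(precision)) 1 - precision else {
    undefined <- c(undefined, "fdr"); NaN }

  peak_pos <- NaN; p2p <- NaN
  if (tp > 0) {
    d <- match$detected[match$pairs$det_idx, , drop = FALSE]
    g <- match$truth[match$pairs$truth_idx, , drop = FALSE]
    dt_true <- g$t_neg_s - g$t_pos_s
    pos_err <- (abs(d$t_pos_s - g$t_pos_s) + abs(d$t_neg_s - g$t_neg_s)) / 2
    peak_pos <- mean(pos_err / dt_true) * 100
    p2p_true <- truth_p2p(g)
    p2p <- mean(abs(d$dV_V - p2p_true) / p2p_true) * 100
  } else {
    undefined <- c(undefined, "peak_pos_err_pct", "p2p_err_pct")
  }
  out <- data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
                    recall = recall, f1 = f1, fdr = fdr,
                    peak_pos_err_pct = peak_pos, p2p_err_pct = p2p)
  class(out) <- c("detection_metrics", "data.frame")
  attr(out, "undefined") <- undefined
  out
}

#' Benchmark both detectors over flow-rate/bandwidth conditions
#'
#' For every (flow, bandwidth) condition and method: tunes the method's
#' threshold to balance precision and recall on a dedicated tuning stream,
#' then runs `n_seeds` fresh streams (identical streams across methods —
#' paired design) and collects the metrics per seed.
#'
#' @param conditions data.frame with columns `Q_uL_min` and `BW_Hz`.
#' @param methods Character vector among `"derivative"`, `"baseline"`.
#' @param n_seeds Streams per condition.
#' @param base_config A [sim_config()] supplying all other parameters.
#' @param master_seed Integer; all stream and tuning seeds derive from it.
#' @return Tidy data.frame keyed by (`Q_uL_min`, `BW_Hz`, `method`, `seed`)
#'   with the [compute_metrics()] columns and the tuned `threshold`.
#' @export
benchmark_sweep <- function(conditions, methods = c("derivative", "baseline"),
                            n_seeds = 10, base_config = sim_config(),
                            master_seed = 1) {
  stopifnot(nrow(conditions) > 0)
  seeds <- derive_seeds(master_seed, (n_seeds + 1L) * nrow(conditions))
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cfg <- base_config
    cfg$Q_uL_min <- conditions$Q_uL_min[ci]
    cfg$BW_Hz <- conditions$BW_Hz[ci]
    cfg <- validate_sim_config(cfg)
    kin <- derive_kinematics(cfg)
    tol <- kin$delta_s / 2
    block <- seeds[((ci - 1L) * (n_seeds + 1L) + 1L):(ci * (n_seeds + 1L))]
    tune_cfg <- cfg; tune_cfg$seed <- block[1L]
    tune_stream <- synthesize_stream(tune_cfg, keep_components = FALSE)
    thresholds <- lapply(stats::setNames(methods, methods), function(m)
      tryCatch(tune_balanced_threshold(m, tune_stream, tol_s = tol)$threshold,
               error = function(e) NA_real_))
    for (si in seq_len(n_seeds)) {
      scfg <- cfg; scfg$seed <- block[si + 1L]
      stream <- synthesize_stream(scfg, keep_components = FALSE)
      for (m in methods) {
        row <- tryCatch({
          ev <- if (m == "derivative")
            run_pipeline(stream$trace, detector_config_for(scfg),
                         theta = thresholds[[m]])
          else
            baseline_detect(stream$trace, baseline_config_for(scfg),
                            theta = thresholds[[m]])
          met <- compute_metrics(match_events(ev, stream$truth,
                                              match_config(tol_s = tol)))
          cbind(data.frame(Q_uL_min = cfg$Q_uL_min, BW_Hz = cfg$BW_Hz,
                           method = m, seed = scfg$seed,
                           threshold = thresholds[[m]]),
                as.data.frame(met))
        }, error = function(e) {
          data.frame(Q_uL_min = cfg$Q_uL_min, BW_Hz = cfg$BW_Hz, method = m,
                     seed = scfg$seed, threshold = thresholds[[m]],
                     tp = NA, fp = NA, fn = NA, precision = NA, recall = NA,
                     f1 = NA, fdr = NA, peak_pos_err_pct = NA,
                     p2p_err_pct = NA)
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The standard bandwidth-by-flow-rate benchmark grid
#'
#' The four paired acquisition conditions used for the 2 um benchmark:
#' 0.3 uL/min at 100 Hz, 1 at 300, 2 at 500, 3 at 1000.
#'
#' @return data.frame with columns `Q_uL_min`, `BW_Hz`.
#' @export
benchmark_conditions <- function() {
  data.frame(Q_uL_min = c(0.3, 1, 2, 3), BW_Hz = c(100, 300, 500, 1000))
}
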