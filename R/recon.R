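#' Features from event landmarks
#'
#' Reads the peak values from the raw (not derivative) trace at the landmark
#' indices and forms the two biophysical features: peak-to-peak amplitude
#' `dV = v_pos - v_neg` and transit time `dt = |t_neg - t_pos|`.
#'
#' @param raw A [signal_trace()].
#' @param pos_idx,neg_idx Integer landmark indices of the positive and
#'   negative raw-signal peaks.
#' @return List with `dV_V`, `dt_s`, `v_pos_V`, `v_neg_V`.
#' @export
features_from_landmarks <- function(raw, pos_idx, neg_idx) {
  stopifnot(inherits(raw, "signal_trace"))
  n <- length(raw$samples)
  if (any(c(pos_idx, neg_idx) < 1L) || any(c(pos_idx, neg_idx) > n))
    stop("landmark index out of trace bounds")
  v_pos <- raw$samples[pos_idx]
  v_neg <- raw$samples[neg_idx]
  if (v_pos <= v_neg)
    stop("inverted polarity: v_pos <= v_neg (event rejected)")
  list(dV_V = v_pos - v_neg, dt_s = abs(neg_idx - pos_idx) / raw$fs,
       v_pos_V = v_pos, v_neg_V = v_neg)
}

#' Fit a bi-Gaussian model to one detected event
#'
#' Closed-form initialization from the landmarks (`A = dV/2`, `delta = dt`,
#' `t0` = peak midpoint, `sigma = dt/4`) with optional window-local
#' least-squares refinement (Levenberg-Marquardt, at most 50 iterations).
#' Refinement that fails to converge, or would move `t0` outside the event
#' window, falls back to the initialization with `refined = FALSE`.
#'
#' @param raw A [signal_trace()].
#' @param event One row of a detected-event data.frame (needs `dV_V`, `dt_s`,
#'   `t_pos_s`, `t_neg_s`, `left_idx`, `right_idx`).
#' @param refine Attempt least-squares refinement (default TRUE).
#' @return List of class `bigaussian_fit` with `A_V`, `sigma_s`, `delta_s`,
#'   `t0_s`, `refined` (logical), `rmse_V` (residual RMSE over the window,
#'   NA when not refined).
#' @export
fit_bigaussian <- function(raw, event, refine = TRUE) {
  stopifnot(inherits(raw, "signal_trace"))
  init <- list(A_V = event$dV_V / 2, sigma_s = event$dt_s / 4,
               delta_s = event$dt_s,
               t0_s = (event$t_pos_s + event$t_neg_s) / 2,
               refined = FALSE, rmse_V = NA_real_)
  class(init) <- "bigaussian_fit"
  if (!refine) return(init)
  if (is.na(event$left_idx) || is.na(event$right_idx) ||
      event$right_idx - event$left_idx < 4L) {
    attr(init, "flag") <- "degenerate-window"
    return(init)
  }
  # fit window: the event window padded by two lobe widths so the Gaussian
  # tails anchor the local baseline
  pad <- round(2 * init$sigma_s * raw$fs)
  li <- max(1L, event$left_idx - pad)
  ri <- min(length(raw$samples), event$right_idx + pad)
  idx <- li:ri
  tt <- idx_to_time(idx, raw$fs, raw$t_start)
  yy <- raw$samples[idx]
  # t0 stays inside the detected event window [left_zc, right_zc]
  t_lo <- idx_to_time(max(1L, event$left_idx), raw$fs, raw$t_start)
  t_hi <- idx_to_time(min(length(raw$samples), event$right_idx),
                      raw$fs, raw$t_start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A * (exp(-(tt - t0 + d / 2)^2 / (2 * sg^2)) -
                exp(-(tt - t0 - d / 2)^2 / (2 * sg^2))),
      start = list(A = init$A_V, d = init$delta_s, sg = init$sigma_s,
                   t0 = init$t0_s),
      lower = c(0, 2 / raw$fs, 0.5 / raw$fs, t_lo),
      upper = c(Inf, Inf, Inf, t_hi),
      control = minpack.lm::nls.lm.control(maxiter = 50)),
    error = function(e) NULL)
  if (is.null(fit)) {
    attr(init, "flag") <- "refinement-failed"
    return(init)
  }
  p <- as.list(stats::coef(fit))
  if (p$t0 < t_lo || p$t0 > t_hi || p$A <= 0 || p$sg <= 0 || p$d <= 0) {
    attr(init, "flag") <- "refinement-out-of-window"
    return(init)
  }
  out <- list(A_V = p$A, sigma_s = p$sg, delta_s = p$d, t0_s = p$t0,
              refined = TRUE,
              rmse_V = sqrt(mean(stats::resid(fit)^2)))
  class(out) <- "bigaussian_fit"
  out
}

#' Fit every detected event of a table
#'
#' @param raw A [signal_trace()].
#' @param events Detected-event data.frame.
#' @param refine Passed to [fit_bigaussian()].
#' @return data.frame with one row per event: `event_id`, `A_V`, `sigma_s`,
#'   `delta_s`, `t0_s`, `refined`.
#' @export
fit_events <- function(raw, events, refine = TRUE) {
  if (!nrow(events))
    return(data.frame(event_id = integer(), A_V = numeric(),
                      sigma_s = numeric(), delta_s = numeric(),
                      t0_s = numeric(), refined = logical()))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    f <- fit_bigaussian(raw, events[i, ], refine = refine)
    data.frame(event_id = events$event_id[i], A_V = f$A_V,
               sigma_s = f$sigma_s, delta_s = f$delta_s, t0_s = f$t0_s,
               refined = f$refined)
  })
  do.call(rbind, rows)
}

#' Reconstruct a smoothed trace from fitted event parameters
#'
#' Sums the analytic bi-Gaussian of every fitted event on the grid; zero
#' elsewhere. Linear in the event list.
#'
#' @param params data.frame with columns `A_V`, `sigma_s`, `delta_s`, `t0_s`
#'   (one row per event), e.g. from [fit_events()].
#' @param n Number of grid samples.
#' @param fs Sampling rate (Sa/s).
#' @param t_start Time of the first sample (s).
#' @return A [signal_trace()].
#' @export
reconstruct_trace <- function(params, n, fs, t_start = 0) {
  out <- numeric(n)
  for (k in seq_len(nrow(params))) {
    out <- out + render_event(list(t0_s = params$t0_s[k],
                                   A_V = params$A_V[k],
                                   delta_s = params$delta_s[k],
                                   sigma_s = params$sigma_s[k]),
                              n, fs, t_start)
  }
  signal_trace(out, fs, t_start)
}
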