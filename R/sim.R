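#' Transit kinematics implied by flow and geometry
#'
#' Converts flow rate and channel/electrode geometry into the mean plug-flow
#' velocity, the expected separation delta between the positive and negative
#' pulse peaks (electrode pitch / velocity), and the Gaussian lobe width
#' sigma (half the single-electrode transit time).
#'
#' @param config A [sim_config()].
#' @return List with `v_um_s`, `delta_s`, `sigma_s`.
#' @export
derive_kinematics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # uL/min -> um^3/s: 1 uL = 1e9 um^3
  q_um3_s <- config$Q_uL_min * 1e9 / 60
  v_um_s <- q_um3_s / config$channel_side_um^2
  delta_s <- config$electrode_pitch_um / v_um_s
  sigma_s <- (config$electrode_width_um / v_um_s) / 2
  if (!all(c(v_um_s, delta_s, sigma_s) > 0))
    stop("invalid sim_config: non-positive kinematics")
  list(v_um_s = v_um_s, delta_s = delta_s, sigma_s = sigma_s)
}

#' Draw ground-truth transit events
#'
#' Homogeneous Poisson arrivals at rate rho * Q, diameters Normal(D, CV*D)
#' truncated at zero, amplitudes from the volume law A = c d^3, and peak times
#' t0 -/+ delta/2. Consumes the current RNG stream; seed beforehand (or use
#' [synthesize_stream()], which seeds from the config).
#'
#' @param config A [sim_config()].
#' @return data.frame of class `true_events` with one row per event:
#'   `t0_s`, `d_um`, `A_V`, `delta_s`, `sigma_s`, `t_pos_s`, `t_neg_s`,
#'   `label`. Sorted by `t0_s`.
#' @export
sample_true_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  kin <- derive_kinematics(config)
  # events/s: rho (#/uL) * Q (uL/min) / 60
  lambda <- config$rho_per_uL * config$Q_uL_min / 60
  n <- stats::rpois(1L, lambda * config$duration_s)
  t0 <- sort(stats::runif(n, 0, config$duration_s))
  d <- stats::rnorm(n, config$D_um, config$CV * config$D_um)
  bad <- which(d <= 0)
  while (length(bad)) {  # truncate at zero by resampling
    d[bad] <- stats::rnorm(length(bad), config$D_um, config$CV * config$D_um)
    bad <- bad[d[bad] <= 0]
  }
  ev <- data.frame(
    t0_s = t0, d_um = d, A_V = config$amp_coeff_V_per_um3 * d^3,
    delta_s = rep.int(kin$delta_s, n), sigma_s = rep.int(kin$sigma_s, n),
    t_pos_s = t0 - kin$delta_s / 2, t_neg_s = t0 + kin$delta_s / 2,
    label = rep.int(paste0(format(config$D_um, trim = TRUE), "um"), n)
  )
  class(ev) <- c("true_events", "data.frame")
  ev
}

#' Evaluate one bipolar Gaussian pulse on a time grid
#'
#' The canonical two-electrode transit waveform: a positive and a negative
#' Gaussian lobe of equal amplitude and width, symmetric about the event
#' centre:
#' `A exp(-(t - t0 + delta/2)^2 / (2 sigma^2)) - A exp(-(t - t0 - delta/2)^2 / (2 sigma^2))`.
#'
#' @param t Numeric vector of times (s).
#' @param A_V Lobe amplitude (V).
#' @param delta_s Peak separation (s).
#' @param sigma_s Lobe width (s).
#' @param t0_s Event centre (s).
#' @return Numeric vector of signal values (V) at `t`.
#' @export
bigaussian_pulse <- function(t, A_V, delta_s, sigma_s, t0_s) {
  A_V * (exp(-(t - t0_s + delta_s / 2)^2 / (2 * sigma_s^2)) -
         exp(-(t - t0_s - delta_s / 2)^2 / (2 * sigma_s^2)))
}

#' Analytic peak locations and value of a bipolar Gaussian pulse
#'
#' Solves for the true extrema of the pulse (they sit slightly inside
#' t0 -/+ delta/2 because the opposite lobe's tail pulls them together) and
#' returns the peak offset and the peak-to-peak amplitude.
#'
#' @param A_V,delta_s,sigma_s Pulse parameters.
#' @return List with `t_offset_s` (positive-peak offset before the centre),
#'   `peak_V` (positive-peak value) and `p2p_V` (= 2 * peak value).
#' @export
bigaussian_peaks <- function(A_V, delta_s, sigma_s) {
  dfun <- function(t) {  # analytic first derivative, centre at 0
    a <- -delta_s / 2; b <- delta_s / 2
    A_V * (-(t - a) / sigma_s^2 * exp(-(t - a)^2 / (2 * sigma_s^2)) +
            (t - b) / sigma_s^2 * exp(-(t - b)^2 / (2 * sigma_s^2)))
  }
  root <- stats::uniroot(dfun, lower = -delta_s / 2 - 4 * sigma_s,
                         upper = -1e-12 * sigma_s - delta_s / 2 + sigma_s,
                         tol = 1e-15 * max(sigma_s, 1))
  t_peak <- root$root
  peak <- bigaussian_pulse(t_peak, A_V, delta_s, sigma_s, 0)
  list(t_offset_s = -t_peak, peak_V = peak, p2p_V = 2 * peak)
}

#' Render one event onto a sample grid
#'
#' Exact analytic evaluation of the bipolar Gaussian; events fully outside
#' the grid yield a zero trace with a warning.
#'
#' @param ev One-row data.frame (or list) with `t0_s`, `A_V`, `delta_s`,
#'   `sigma_s`.
#' @param n Number of grid samples.
#' @param fs Sampling rate (Sa/s).
#' @param t_start Time of the first grid sample (s).
#' @return Numeric vector of length `n`.
#' @export
render_event <- function(ev, n, fs, t_start = 0) {
  out <- numeric(n)
  half <- ev$delta_s / 2 + 10 * ev$sigma_s
  i0 <- max(1L, ceiling((ev$t0_s - half - t_start) * fs) + 1L)
  i1 <- min(n, floor((ev$t0_s + half - t_start) * fs) + 1L)
  if (i0 > i1) {
    warning("event lies outside the sample grid; rendered as zero")
    return(out)
  }
  t <- idx_to_time(i0:i1, fs, t_start)
  out[i0:i1] <- bigaussian_pulse(t, ev$A_V, ev$delta_s, ev$sigma_s, ev$t0_s)
  out
}

# superpose all truth events on a grid (local windows, exact within 10 sigma)
render_events <- function(truth, n, fs, t_start = 0) {
  out <- numeric(n)
  if (!nrow(truth)) return(out)
  half <- truth$delta_s / 2 + 10 * truth$sigma_s
  i0 <- pmax(1L, ceiling((truth$t0_s - half - t_start) * fs) + 1L)
  i1 <- pmin(n, floor((truth$t0_s + half - t_start) * fs) + 1L)
  for (k in seq_len(nrow(truth))) {
    if (i0[k] > i1[k]) next
    idx <- i0[k]:i1[k]
    t <- idx_to_time(idx, fs, t_start)
    out[idx] <- out[idx] + bigaussian_pulse(t, truth$A_V[k], truth$delta_s[k],
                                            truth$sigma_s[k], truth$t0_s[k])
  }
  out
}

# per-stage cutoff giving a cascade of n identical one-pole stages a final
# -3 dB point at BW
stage_cutoff_hz <- function(BW_Hz, n_stages) {
  BW_Hz / sqrt(2^(1 / n_stages) - 1)
}

#' Cascade of first-order low-pass stages
#'
#' Applies `n_stages` identical discrete one-pole low-pass filters (pole from
#' the matched-z discretization of the analog prototype, zero initial state).
#' The per-stage cutoff is `BW / sqrt(2^(1/n) - 1)` so the cascade's -3 dB
#' point lands at `BW`.
#'
#' @param x Numeric vector (or `signal_trace`) to filter.
#' @param n_stages Number of stages (>= 1).
#' @param BW_Hz Final -3 dB bandwidth (Hz); must be below Nyquist.
#' @param fs Sampling rate (Sa/s); taken from the trace if `x` is one.
#' @return Filtered object of the same kind as `x`.
#' @export
filter_noise <- function(x, n_stages, BW_Hz, fs = NULL) {
  is_trace <- inherits(x, "signal_trace")
  if (is_trace) { fs <- x$fs; v <- x$samples } else v <- as.numeric(x)
  if (is.null(fs)) stop("fs required when filtering a bare vector")
  if (BW_Hz >= fs / 2) stop("invalid config: BW_Hz must be below Nyquist fs/2")
  f1 <- stage_cutoff_hz(BW_Hz, n_stages)
  a <- 1 - exp(-2 * pi * f1 / fs)
  for (k in seq_len(n_stages))
    v <- as.numeric(stats::filter(a * v, 1 - a, method = "recursive"))
  if (is_trace) signal_trace(v, fs, x$t_start) else v
}

# optional slow baseline-drift component
render_drift <- function(drift, t) {
  if (is.null(drift)) return(numeric(length(t)))
  if (drift$type == "sine") {
    f <- if (is.null(drift$freq_Hz)) 2 else drift$freq_Hz
    ph <- if (is.null(drift$phase)) 0 else drift$phase
    drift$amplitude_V * sin(2 * pi * f * t + ph)
  } else {  # linear ramp over the grid span
    drift$amplitude_V * (t - t[1]) / (t[length(t)] - t[1])
  }
}

#' Synthesize a complete demodulated IFC stream with ground truth
#'
#' Builds `s(t) = e(t) + b(t) + n(t)`: the exact superposition of bipolar
#' Gaussian transit events with Poisson arrivals, an optional slow baseline
#' drift, and white noise of standard deviation `sigmaN_V` passed through the
#' n-stage low-pass cascade. Identical config + seed gives a bit-identical
#' stream.
#'
#' @param config A [sim_config()]. If `config$seed` is set the RNG is seeded
#'   with it; otherwise the current RNG stream is consumed.
#' @param keep_components Keep the separate `e`, `b`, `n` traces (default
#'   TRUE).
#' @return An object of class `pulse_stream`: list with `trace`
#'   (`signal_trace`), `truth` (`true_events`), `components` (list of numeric
#'   vectors `e`, `b`, `n` or NULL), `config`, `kinematics`.
#' @export
synthesize_stream <- function(config, keep_components = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$duration_s * config$fs_Sa_s)
  fs <- config$fs_Sa_s
  truth <- sample_true_events(config)
  e <- render_events(truth, n, fs)
  t <- idx_to_time(seq_len(n), fs)
  b <- render_drift(config$drift, t)
  nz <- if (config$sigmaN_V > 0)
    filter_noise(stats::rnorm(n, 0, config$sigmaN_V), config$n_stages,
                 config$BW_Hz, fs)
  else numeric(n)
  s <- e + b + nz
  structure(list(trace = signal_trace(s, fs),
                 truth = truth,
                 components = if (keep_components) list(e = e, b = b, n = nz),
                 config = config,
                 kinematics = derive_kinematics(config)),
            class = "pulse_stream")
}

#' @export
print.pulse_stream <- function(x, ...) {
  cat(sprintf("<pulse_stream> %d samples (%g s @ %g Sa/s), %d true events\n",
              length(x$trace$samples), x$config$duration_s, x$trace$fs,
              nrow(x$truth)))
  invisible(x)
}

#' Analytic ground-truth peak-to-peak amplitude of true events
#'
#' @param truth A `true_events` table.
#' @return Numeric vector of peak-to-peak amplitudes (V), one per event.
#' @export
truth_p2p <- function(truth) {
  if (!nrow(truth)) return(numeric(0))
  # delta/sigma is shared within a stream; scale by A which varies per event
  pk <- bigaussian_peaks(1, truth$delta_s[1], truth$sigma_s[1])
  truth$A_V * pk$p2p_V
}
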