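#' Uniformly sampled signal trace
#'
#' The universal currency between modules: an ordered vector of demodulated
#' impedance-magnitude samples (volts) on a uniform time grid.
#'
#' @param samples Numeric vector of at least 2 finite values (V).
#' @param fs Sampling rate in samples per second.
#' @param t_start Time of the first sample (s).
#' @return An object of class `signal_trace` with elements `samples`, `fs`,
#'   `t_start`.
#' @export
signal_trace <- function(samples, fs, t_start = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("signal_trace needs at least 2 samples")
  if (!all(is.finite(samples))) stop("signal_trace samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = fs, t_start = t_start),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %.6g Sa/s, t = [%.6g, %.6g] s\n",
              length(x$samples), x$fs, x$t_start,
              x$t_start + (length(x$samples) - 1L) / x$fs))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Time stamps of a trace
#'
#' @param trace A `signal_trace`.
#' @return Numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  trace$t_start + (seq_along(trace$samples) - 1L) / trace$fs
}

#' First-derivative trace
#'
#' Same grid as its source signal, values in V/s.
#'
#' @param values Numeric vector of derivative samples (V/s).
#' @param fs Sampling rate (Sa/s).
#' @param t_start Time of first sample (s).
#' @return An object of class `derivative_trace`.
#' @export
derivative_trace <- function(values, fs, t_start = 0) {
  structure(list(values = as.numeric(values), fs = fs, t_start = t_start),
            class = "derivative_trace")
}

#' @export
print.derivative_trace <- function(x, ...) {
  cat(sprintf("<derivative_trace> %d samples @ %.6g Sa/s\n",
              length(x$values), x$fs))
  invisible(x)
}

# index (1-based) -> time in seconds on a trace grid
idx_to_time <- function(idx, fs, t_start = 0) t_start + (idx - 1) / fs
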