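#' Simulation configuration for synthetic IFC streams
#'
#' Defaults reproduce the standard synthetic acquisition conditions: 2 um
#' polystyrene beads at 5% diameter CV, 1e3 particles/uL, 2 uL/min through a
#' 30 um x 30 um channel with two 20 um electrodes at 20 um spacing, a 4-stage
#' first-order low-pass with 500 Hz final -3 dB bandwidth, 115.1 kSa/s
#' sampling, 1.3 uV white-noise standard deviation, 30 s streams.
#'
#' @param D_um Nominal particle diameter (um).
#' @param CV Fractional coefficient of variation of the diameter.
#' @param rho_per_uL Particle concentration (#/uL).
#' @param Q_uL_min Volumetric flow rate (uL/min).
#' @param n_stages Number of identical first-order low-pass stages (>= 1).
#' @param BW_Hz Final -3 dB bandwidth of the filter cascade (Hz).
#' @param fs_Sa_s Sampling rate (Sa/s).
#' @param sigmaN_V White-noise standard deviation before filtering (V).
#' @param duration_s Stream duration (s).
#' @param channel_side_um Side of the square microchannel (um).
#' @param electrode_pitch_um Centre-to-centre distance between the two sensing
#'   regions (um); default 40 = 20 um electrode width + 20 um spacing.
#' @param electrode_width_um Width of one electrode (um); sets the pulse rise
#'   scale.
#' @param amp_coeff_V_per_um3 Amplitude coefficient c in the Coulter-type
#'   volume law A(d) = c d^3 (V/um^3). The default 4.8e-8 puts a 2 um bead at
#'   a post-filter SNR of about 3 under the default noise settings.
#' @param drift Optional baseline-drift descriptor: a list with `type`
#'   ("sine" or "ramp"), `amplitude_V`, and for sine `freq_Hz` (default 2) and
#'   `phase` (radians, default 0). `NULL` (default) disables drift.
#' @param seed Optional RNG seed recorded in the config and applied by
#'   [synthesize_stream()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(D_um = 2, CV = 0.05, rho_per_uL = 1e3, Q_uL_min = 2,
                       n_stages = 4L, BW_Hz = 500, fs_Sa_s = 115100,
                       sigmaN_V = 1.3e-6, duration_s = 30,
                       channel_side_um = 30, electrode_pitch_um = 40,
                       electrode_width_um = 20,
                       amp_coeff_V_per_um3 = 4.8e-8,
                       drift = NULL, seed = NULL) {
  cfg <- list(D_um = D_um, CV = CV, rho_per_uL = rho_per_uL,
              Q_uL_min = Q_uL_min, n_stages = as.integer(n_stages),
              BW_Hz = BW_Hz, fs_Sa_s = fs_Sa_s, sigmaN_V = sigmaN_V,
              duration_s = duration_s, channel_side_um = channel_side_um,
              electrode_pitch_um = electrode_pitch_um,
              electrode_width_um = electrode_width_um,
              amp_coeff_V_per_um3 = amp_coeff_V_per_um3,
              drift = drift, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("D_um", "rho_per_uL", "Q_uL_min", "BW_Hz", "fs_Sa_s",
           "duration_s", "channel_side_um", "electrode_pitch_um",
           "electrode_width_um", "amp_coeff_V_per_um3")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("sim_config field '%s' must be a single positive number", f))
  }
  if (!is.numeric(cfg$CV) || cfg$CV < 0) stop("sim_config field 'CV' must be >= 0")
  if (!is.numeric(cfg$sigmaN_V) || cfg$sigmaN_V < 0)
    stop("sim_config field 'sigmaN_V' must be >= 0")
  if (cfg$n_stages < 1L) stop("sim_config field 'n_stages' must be >= 1")
  if (cfg$BW_Hz >= cfg$fs_Sa_s / 2)
    stop("invalid sim_config: 'BW_Hz' must be below the Nyquist rate 'fs_Sa_s'/2")
  n <- round(cfg$duration_s * cfg$fs_Sa_s)
  if (n < 2) stop("duration_s * fs_Sa_s must give at least 2 samples")
  if (!is.null(cfg$drift)) {
    d <- cfg$drift
    if (!is.list(d) || is.null(d$type) || !d$type %in% c("sine", "ramp"))
      stop("drift must be a list with type 'sine' or 'ramp'")
    if (is.null(d$amplitude_V) || d$amplitude_V < 0)
      stop("drift$amplitude_V must be >= 0")
    if (d$type == "sine" && is.null(d$freq_Hz)) cfg$drift$freq_Hz <- 2
    if (d$type == "sine" && is.null(d$phase)) cfg$drift$phase <- 0
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> D=%g um (CV %g%%), rho=%g/uL, Q=%g uL/min, ",
                     "%d-stage LPF @ %g Hz, fs=%g Sa/s, sigmaN=%g V, %g s\n"),
              x$D_um, 100 * x$CV, x$rho_per_uL, x$Q_uL_min, x$n_stages,
              x$BW_Hz, x$fs_Sa_s, x$sigmaN_V, x$duration_s))
  invisible(x)
}

#' Derivative-detector configuration
#'
#' @param threshold_V_s Absolute derivative threshold theta (V/s), or `NULL`
#'   to auto-resolve from the robust noise scale via `auto_k`.
#' @param auto_k Multiplier for MAD-based auto-thresholding (used when
#'   `threshold_V_s` is `NULL`).
#' @param min_lobe_samples Minimum length of a supra-threshold run.
#' @param max_gap_s Maximum time between the paired slope lobes of one event.
#' @param refractory_s Minimum separation between distinct events; closer
#'   detections are merged keeping the larger peak-to-peak amplitude. Use 0 to
#'   disable merging.
#' @param polarity `"positive-first"` (default: positive raw peak precedes the
#'   negative one, the standard two-electrode transit signature) or
#'   `"negative-first"` for inverted wiring.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(threshold_V_s = NULL, auto_k = 5,
                            min_lobe_samples = 3L, max_gap_s = 5e-3,
                            refractory_s = 5e-4,
                            polarity = c("positive-first", "negative-first")) {
  polarity <- match.arg(polarity)
  if (!is.null(threshold_V_s) && threshold_V_s <= 0)
    stop("threshold_V_s must be > 0")
  if (is.null(threshold_V_s) && auto_k <= 0) stop("auto_k must be > 0")
  if (min_lobe_samples < 1L) stop("min_lobe_samples must be >= 1")
  if (max_gap_s <= 0) stop("max_gap_s must be > 0")
  if (refractory_s < 0) stop("refractory_s must be >= 0")
  structure(list(threshold_V_s = threshold_V_s, auto_k = auto_k,
                 min_lobe_samples = as.integer(min_lobe_samples),
                 max_gap_s = max_gap_s, refractory_s = refractory_s,
                 polarity = polarity),
            class = "detector_config")
}

#' Detector configuration matched to a simulation's kinematics
#'
#' Sets `max_gap_s` to the expected peak separation delta and `refractory_s`
#' to delta/2 for the flow/geometry of a simulation config.
#'
#' @param sim A `sim_config`.
#' @param ... Further arguments passed to [detector_config()].
#' @return A `detector_config`.
#' @export
detector_config_for <- function(sim, ...) {
  kin <- derive_kinematics(sim)
  args <- list(...)
  if (is.null(args$max_gap_s)) args$max_gap_s <- kin$delta_s
  if (is.null(args$refractory_s)) args$refractory_s <- kin$delta_s / 2
  do.call(detector_config, args)
}

#' Amplitude-thresholding baseline configuration
#'
#' The multi-stage comparator: moving-median baseline estimation, two-sided
#' amplitude thresholding of the detrended signal, and pairing of positive
#' with following negative excursions.
#'
#' @param amp_threshold_V Raw-amplitude threshold (V), or `NULL` to
#'   auto-resolve as `auto_k` times the robust noise scale of the detrended
#'   signal.
#' @param auto_k Multiplier for auto-thresholding.
#' @param baseline_window_s Moving-median window for drift estimation (s).
#' @param min_event_samples Minimum supra-threshold run length.
#' @param pair_gap_s Maximum separation between a positive excursion and the
#'   following negative excursion of the same event.
#' @param detrend Logical; apply the moving-median detrending stage. Disabling
#'   it exposes the comparator's sensitivity to baseline drift.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(amp_threshold_V = NULL, auto_k = 4,
                            baseline_window_s = 0.02,
                            min_event_samples = 3L, pair_gap_s = 5e-3,
                            detrend = TRUE) {
  if (!is.null(amp_threshold_V) && amp_threshold_V <= 0)
    stop("amp_threshold_V must be > 0")
  if (is.null(amp_threshold_V) && auto_k <= 0) stop("auto_k must be > 0")
  if (baseline_window_s <= 0) stop("baseline_window_s must be > 0")
  if (pair_gap_s <= 0) stop("pair_gap_s must be > 0")
  structure(list(amp_threshold_V = amp_threshold_V, auto_k = auto_k,
                 baseline_window_s = baseline_window_s,
                 min_event_samples = as.integer(min_event_samples),
                 pair_gap_s = pair_gap_s, detrend = isTRUE(detrend)),
            class = "baseline_config")
}

#' Baseline configuration matched to a simulation's kinematics
#'
#' @param sim A `sim_config`.
#' @param ... Further arguments passed to [baseline_config()].
#' @return A `baseline_config`.
#' @export
baseline_config_for <- function(sim, ...) {
  kin <- derive_kinematics(sim)
  args <- list(...)
  if (is.null(args$pair_gap_s)) args$pair_gap_s <- 2 * kin$delta_s
  do.call(baseline_config, args)
}
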