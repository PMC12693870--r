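#' Write a signal trace to CSV
#'
#' Plain-text container: `#`-prefixed metadata lines carrying the mandatory
#' sampling-rate metadata, then `time_s,signal_V` rows. Values are written
#' with 15 significant digits so a read round trip is exact to well beyond 12
#' digits.
#'
#' @param trace A [signal_trace()].
#' @param path Output path (`.csv`). HDF5 (`.h5`) is not supported by this
#'   package; an informative error is raised.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  check_csv_ext(path)
  con <- file(path, "w")
  writeLines(c("# pulsekit signal trace",
               sprintf("# fs_Sa_s=%.15g", trace$fs),
               sprintf("# t_start_s=%.15g", trace$t_start)), con)
  close(con)
  dt <- data.table::data.table(time_s = trace_times(trace),
                               signal_V = trace$samples)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

check_csv_ext <- function(path) {
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE))
    stop("HDF5 containers are not supported; use the CSV trace format")
  invisible(path)
}

#' Read a signal trace from CSV
#'
#' Requires the `fs_Sa_s` metadata line (the sampling rate is never guessed
#' from timestamps) and rejects non-uniform time stamps (jitter beyond
#' 1e-6 of a sample interval).
#'
#' @param path CSV written by [write_trace()].
#' @return A [signal_trace()].
#' @export
read_trace <- function(path) {
  check_csv_ext(path)
  if (!file.exists(path)) stop("no such file: ", path)
  head <- readLines(path, n = 10L)
  meta <- head[startsWith(head, "#")]
  fs_line <- grep("fs_Sa_s=", meta, value = TRUE)
  if (!length(fs_line))
    stop("missing fs_Sa_s metadata in ", path, " (sampling rate is never guessed)")
  fs <- as.numeric(sub(".*fs_Sa_s=", "", fs_line[1L]))
  ts_line <- grep("t_start_s=", meta, value = TRUE)
  t_start <- if (length(ts_line)) as.numeric(sub(".*t_start_s=", "", ts_line[1L])) else 0
  dt <- data.table::fread(path, skip = length(meta))
  if (!all(c("time_s", "signal_V") %in% names(dt)))
    stop("trace CSV must have columns time_s,signal_V")
  tt <- dt$time_s
  if (length(tt) >= 2L) {
    expected <- t_start + (seq_along(tt) - 1L) / fs
    if (max(abs(tt - expected)) > 1e-6 / fs)
      stop("non-uniform timestamps in ", path,
           " (jitter exceeds 1e-6 of a sample interval)")
  }
  signal_trace(dt$signal_V, fs, t_start)
}

#' Write / read event tables
#'
#' Detected events and ground-truth tables as plain CSV with a mandatory
#' header, times in seconds.
#'
#' @param events data.frame (detected events or `true_events`).
#' @param path CSV path.
#' @return Invisibly `path` (write) or the data.frame (read).
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' @rdname write_events
#' @export
read_truth <- function(path) {
  ev <- read_events(path)
  need <- c("t0_s", "t_pos_s", "t_neg_s")
  if (!all(need %in% names(ev)))
    stop("truth CSV must have columns ", paste(need, collapse = ", "))
  class(ev) <- c("true_events", "data.frame")
  ev
}

#' Parse a simulation config file
#'
#' Flat YAML key-value file mirroring the [sim_config()] field names. An
#' empty file yields the all-defaults config. Unknown keys are rejected,
#' listing every offending key; all defaults are echoed into the returned
#' config.
#'
#' @param path YAML file.
#' @return A validated [sim_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(sort(bad), collapse = ", "))
  do.call(sim_config, vals)
}

#' Write a simulation config file
#'
#' @param config A [sim_config()].
#' @param path YAML output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records subcommand, resolved configuration, seeds, paths, package version
#' and per-stage counts next to a run's outputs, sufficient to re-execute the
#' run bit-identically.
#'
#' @param path JSON output path.
#' @param subcommand Character.
#' @param config Resolved config (list).
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of paths.
#' @param counts Named list of per-stage counts/durations.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, subcommand, config = NULL, seed = NULL,
                           inputs = character(), outputs = character(),
                           counts = list()) {
  m <- list(subcommand = subcommand,
            version = as.character(utils::packageVersion("pulsekit")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            seed = seed, config = config,
            inputs = inputs, outputs = outputs, counts = counts)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
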