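# shared fixtures: all generated in code, nothing on disk

# a short default-condition config for unit tests (acceptance runs use the
# full 30 s streams)
quick_config <- function(duration_s = 2, ...) {
  sim_config(duration_s = duration_s, ...)
}

# noiseless trace holding bipolar pulses at given centres
pulse_trace <- function(t0s, A = 10e-6, delta = 1.08e-3, sigma = 0.27e-3,
                        fs = 115100, duration = NULL) {
  if (is.null(duration)) duration <- max(t0s) + 20 * sigma + delta
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  A <- rep_len(A, length(t0s))
  s <- numeric(n)
  for (k in seq_along(t0s))
    s <- s + bigaussian_pulse(t, A[k], delta, sigma, t0s[k])
  signal_trace(s, fs)
}

# detector config with a manual threshold suited to a noiseless pulse trace
manual_cfg <- function(trace, frac = 0.2, delta = 1.08e-3, ...) {
  d <- compute_derivative(trace)
  detector_config(threshold_V_s = frac * max(abs(d$values)),
                  max_gap_s = delta, refractory_s = delta / 2, ...)
}

# Independent brute-force event finder: enumerates supra-threshold sign runs
# directly from index sets and scans every (+,-) grouping by explicit
# look-ahead. Written as a deliberate re-derivation of the detection grammar
# for cross-checking the single-pass implementation; returns (pos, neg) peak
# index pairs.
brute_force_events <- function(v, s, theta, min_lobe, gap_n) {
  n <- length(v)
  idx <- which(abs(v) > theta)
  if (!length(idx)) return(matrix(integer(), ncol = 2))
  brk <- c(0, which(diff(idx) > 1), length(idx))
  runs <- list()
  for (b in seq_len(length(brk) - 1)) {
    chunk <- idx[(brk[b] + 1):brk[b + 1]]
    sg <- sign(v[chunk])
    sub_brk <- c(0, which(diff(sg) != 0), length(chunk))
    for (u in seq_len(length(sub_brk) - 1)) {
      piece <- chunk[(sub_brk[u] + 1):sub_brk[u + 1]]
      if (length(piece) >= min_lobe)
        runs[[length(runs) + 1]] <- list(start = piece[1],
                                         end = piece[length(piece)],
                                         sign = sign(v[piece[1]]))
    }
  }
  zc <- function(from, to, down) {
    if (to <= from) return(NA_integer_)
    ks <- integer(0)
    for (k in from:(to - 1)) {
      if (down && v[k] >= 0 && v[k + 1] < 0) ks <- c(ks, k)
      if (!down && v[k] <= 0 && v[k + 1] > 0) ks <- c(ks, k)
    }
    if (!length(ks)) return(NA_integer_)
    k <- if (down) ks[which.max(s[ks])] else ks[which.min(s[ks])]
    frac <- if (v[k] != v[k + 1]) v[k] / (v[k] - v[k + 1]) else 0
    if (frac > 0.5) k + 1L else k
  }
  out <- matrix(integer(), ncol = 2)
  i <- 1
  nr <- length(runs)
  while (i <= nr) {
    r <- runs[[i]]
    if (r$sign > 0 && i + 1 <= nr && runs[[i + 1]]$sign < 0 &&
        runs[[i + 1]]$start - r$end <= gap_n) {
      j <- i + 1
      consumed <- j
      trail <- j + 1 <= nr && runs[[j + 1]]$sign > 0 &&
        runs[[j + 1]]$start - runs[[j]]$end <= gap_n
      trail_lead <- trail && j + 2 <= nr && runs[[j + 2]]$sign < 0 &&
        runs[[j + 2]]$start - runs[[j + 1]]$end <= gap_n
      if (trail && !trail_lead) consumed <- j + 1
      pos <- zc(r$end, runs[[j]]$start, TRUE)
      neg_to <- if (consumed > j) runs[[consumed]]$start
                else min(n, runs[[j]]$end + gap_n)
      neg <- zc(runs[[j]]$end, neg_to, FALSE)
      if (is.na(pos)) {
        span <- r$end:runs[[j]]$start
        pos <- span[which.max(s[span])]
      }
      if (is.na(neg) && neg_to > runs[[j]]$end) {
        span <- runs[[j]]$end:neg_to
        neg <- span[which.min(s[span])]
      }
      left_ok <- any(v[max(1, r$start - gap_n):r$start] <= 0) ||
        max(1, r$start - gap_n) > 1
      right_end <- if (consumed > j) runs[[consumed]]$end else neg
      right_ok <- !is.na(right_end) &&
        (any(v[right_end:min(n, right_end + gap_n)] <= 0) ||
           min(n, right_end + gap_n) < n)
      edge <- r$start <= 2 || runs[[consumed]]$end >= n - 1 ||
        !left_ok || !right_ok
      if (!is.na(pos) && !is.na(neg) && pos < neg && !edge)
        out <- rbind(out, c(pos, neg))
      i <- consumed + 1
    } else i <- i + 1
  }
  out
}

# minimal truth table for matching tests
make_truth <- function(t0, A = 1e-6, delta = 1.08e-3, sigma = 0.27e-3,
                       d = 2, label = "2um") {
  n <- length(t0)
  data.frame(t0_s = t0, d_um = rep(d, n), A_V = rep(A, n),
             delta_s = rep(delta, n), sigma_s = rep(sigma, n),
             t_pos_s = t0 - delta / 2, t_neg_s = t0 + delta / 2,
             label = rep(label, n))
}

# minimal detection table with centres at t (dV defaults to the analytic p2p
# of the matching truth pulse so amplitude errors are zero)
make_det <- function(t, dV = NULL, delta = 1.08e-3, A = 1e-6,
                     sigma = 0.27e-3) {
  n <- length(t)
  if (is.null(dV)) dV <- rep(bigaussian_peaks(A, delta, sigma)$p2p_V, n)
  data.frame(event_id = seq_len(n), t_pos_s = t - delta / 2,
             t_neg_s = t + delta / 2, v_pos_V = dV / 2, v_neg_V = -dV / 2,
             dV_V = dV, dt_s = rep(delta, n),
             left_zc_s = t - delta, right_zc_s = t + delta,
             left_idx = rep(NA_integer_, n), pos_idx = rep(NA_integer_, n),
             neg_idx = rep(NA_integer_, n), right_idx = rep(NA_integer_, n))
}
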