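# pulsekit

Derivative-based event detection and feature extraction for impedance flow
cytometry (IFC) signals, with a full synthetic test bed.

## The problem

IFC measures the electrical impedance of single cells or particles as they
transit a microfluidic channel between two electrode pairs. Each transit
produces a *bipolar* pulse in the demodulated impedance magnitude — one
positive and one negative peak — whose peak-to-peak amplitude ΔV scales with
particle volume and whose transit time Δt encodes velocity. Finding these
events reliably in long, drifting, noisy streams (and doing it fast enough
for real-time use) is the gatekeeper for everything downstream: counting,
sizing, phenotyping.

pulsekit is for people building or evaluating IFC processing pipelines. It
provides:

* a **simulator** of demodulated IFC streams with exact ground truth —
  bipolar Gaussian events with Poisson arrivals, a Coulter volume law
  A(d) = c·d³, diameter CV, band-limited noise (n-stage first-order low-pass
  cascade), optional baseline drift;
* a **single-pass derivative detector**: finite-difference derivative,
  robust MAD thresholding of |s′|, slope-lobe grouping, zero-crossing
  landmarks, ΔV/Δt extraction — O(N), no templates, no training;
* a classical **amplitude-thresholding comparator** (median detrend +
  two-sided threshold + run pairing) behind the same event schema;
* **evaluation**: tolerance-based one-to-one matching against ground truth,
  precision / recall / F1 / FDR, peak-position and peak-to-peak error
  percentages, and a paired flow-rate × bandwidth benchmark;
* **bi-Gaussian reconstruction** of detected events (closed-form
  initialization + local least squares);
* a **decision-tree classifier** on (ΔV, Δt) for particle sizing, with a
  portable JSON model format and chunked streaming classification.

The model: the stream is s(t) = e(t) + b(t) + n(t) (events + drift + noise).
Since the drift is slow, s′(t) ≈ e′(t) + n′(t): differentiation suppresses
baseline wander while each event becomes a (+,−,+) slope signature whose
zero crossings mark the raw-signal peaks.

## Worked example

```r
library(pulsekit)

cfg    <- sim_config(D_um = 4, duration_s = 5, seed = 42)  # 4 um beads
stream <- synthesize_stream(cfg)
stream
#> <pulse_stream> 575500 samples (5 s @ 115100 Sa/s), 184 true events

events <- run_pipeline(stream$trace, detector_config_for(cfg))
sprintf("theta = %.3g V/s, %d events detected", attr(events, "theta"), nrow(events))
#> "theta = 0.00234 V/s, 173 events detected"

head(events[, c("t_pos_s", "t_neg_s", "dV_V", "dt_s")], 3)
#>    t_pos_s  t_neg_s      dV_V     dt_s
#> 1 0.006386 0.007672 3.544e-06 0.001286
#> 2 0.010834 0.011903 4.924e-06 0.001069
#> 3 0.019183 0.020269 4.943e-06 0.001086

tol <- derive_kinematics(cfg)$delta_s / 2     # tau = half the peak separation
compute_metrics(match_events(events, stream$truth, match_config(tol_s = tol)))
#>    tp fp fn precision recall    f1 fdr peak_pos_err_pct p2p_err_pct
#> 1 173  0 11         1   0.94 0.969   0             1.65        6.33

fit_bigaussian(stream$trace, events[2, ])[c("A_V", "delta_s", "sigma_s")]
#> A = 2.5e-06 V, delta = 1.054 ms, sigma = 0.2534 ms
```

Reading the output: the auto threshold lands at 5× the robust noise scale of
the derivative; all 173 detections are true events (precision 1, FDR 0); the
11 misses are almost entirely coincident transits that merge at this event
rate (≈ 37 events/s against a ~1 ms transit). Peak positions are localized
to ~1.7% of the transit time and ΔV to ~6%. The fitted event parameters
(δ ≈ 1.05 ms, σ ≈ 0.25 ms) match the kinematics of 2 µL/min through the
default geometry (δ = 1.08 ms, σ = 0.27 ms).

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pulsekit.R", package = "pulsekit"))')
Rscript $CLI simulate --config sim.yaml --seed 7 --out stream.csv
Rscript $CLI detect   --in stream.csv --threshold auto:5 --out events.csv
Rscript $CLI evaluate --events events.csv --truth stream_truth.csv \
                      --tol 0.00054 --out metrics.json
```

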