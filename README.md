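# duofluor

Analysis of dual-channel fluorescence time-lapse movies from
neurotransmitter sensors with contrasting affinities — a visible,
high-affinity GRAB-type dopamine indicator (Kd in the tens of nM)
imaged simultaneously with a near-infrared nanotube catecholamine
sensor (nIRCat-type, Kd in the tens of µM). The high-affinity channel
saturates in dopamine-rich tissue such as the dorsal striatum; the
low-affinity channel stays linear there and can map localized "high
dopamine" release hotspots. The package is written for imaging labs
doing this kind of two-sensor experiment (evoked release in slices,
spontaneous-wave recordings in developing retina) and for anyone who
needs its individual pieces: ΔF/F extraction, photobleach correction,
zero-phase filtering, grid-ROI mapping, rise–decay kinetics, triggered
averaging, or exact small-sample rank statistics.

## What it computes

* **ΔF/F = (F − F0)/F0** per pixel or per trace, with F0 either the
  pre-stimulus mean or the trial median.
* **Photobleach correction** by fitting and subtracting
  A₁e^(−t/τ₁) + A₂e^(−t/τ₂) + C.
* **Zero-phase low-pass filtering** (third-order Butterworth, 0.68 Hz
  default) with exact DC preservation and half-power gain at the
  cutoff.
* **Grid hotspot mapping**: an 8 × 8 px grid mask; a square is an
  active ROI when its peak ΔF/F after stimulation exceeds the baseline
  mean by 2 baseline SDs, with per-trial peaks averaged over ≥ 3
  stimulations; condition comparison (e.g., D2-agonist suppression)
  reports active-ROI percentage and integrated ΔF/F with fractional
  changes.
* **Kinetics**: nonlinear fits of
  α(1 − e^(−x/τON)) e^(−x/τOFF) + β, whose maximum sits at
  x = τON·ln(1 + τOFF/τON); per-ROI τ distributions.
* **Spontaneous events**: wave detection by z-scored peak finding
  (> 3 SD, ≥ 10 s separation), 60 s event-triggered averages centred
  on the frame before each peak (shared triggers across channels), and
  response amplitudes as the difference of 3 s-smoothed peaks in the
  10 s flanks.
* **Statistics**: paired t (at df = 2, two-sided
  p = 1 − t/√(t² + 2)), Mann–Whitney U with *exact* small-sample p by
  full enumeration (midranks/permutation for ties, normal approximation
  for large samples), and OLS regression with R².
* **A synthetic dual-sensor movie generator** — Hill binding at
  contrasting affinities, Gaussian release hotspots, rise–decay
  kinetics, global calcium-wave transients, double-exponential
  bleaching, Gaussian or Poisson noise — that writes multi-page 16-bit
  TIFFs with JSON sidecars and records full ground truth, so the whole
  pipeline is verifiable offline.

## A worked example

Simulate a three-trial evoked-release experiment and analyse the
low-affinity channel:

```r
library(duofluor)

fx    <- generate_striatal_fixture()                      # 2 channels x 3 trials
dff   <- lapply(fx$nir, compute_dff, baseline_spec("prestim_mean"))
grids <- lapply(dff, apply_grid, square_px = 8)
rois  <- detect_active_rois(grids, stim_frame = fx$truth$stim_frame,
                            k = 2, response_window = fx$truth$response_window)
rois
#> <grid_response_map> 6/64 squares active (k = 2, stim frame 20, window [24, 25], 3 trial(s))
which(rois$active)
#> [1] 10 15 29 36 43 54
identical(which(rois$active), as.integer(fx$truth$active_nir))
#> [1] TRUE
```

All six seeded hotspot squares — and nothing else — cross the 2-SD
criterion. Kinetics of the active squares (the generator's nIR sensor
uses τON = 2 s, τOFF = 6 s; at 1.47 frames/s and trial-level noise the
strong squares recover them to within the sampling limits):

```r
fit_grid(rois)$fits[, c("square", "alpha", "tau_on", "tau_off", "converged")]
#>   square  alpha tau_on tau_off converged
#> 1     10 0.1688   1.71    7.39      TRUE
#> 2     15 0.0094   1.46    7.84      TRUE
#> 3     29 0.1465   1.65    7.50      TRUE
#> 4     36 0.0134   2.68    3.96      TRUE
#> 5     43 0.1279   1.71    7.16      TRUE
#> 6     54 0.0175   2.48    4.92      TRUE
```

A suppressed condition (all release amplitudes × 0.4, the
quinpirole-style contrast):

```r
fq <- generate_striatal_fixture(amplitude_scale = 0.4)
rois_q <- detect_active_rois(lapply(lapply(fq$nir, compute_dff,
                                           baseline_spec("prestim_mean")),
                                    apply_grid, square_px = 8),
                             fq$truth$stim_frame, k = 2,
                             response_window = fq$truth$response_window)
compare_conditions(rois, rois_q)
#> <condition_comparison> active ROIs 9.4% -> 7.8% (change -16.7%);
#>   integrated peak 0.003845 -> 0.001843 (change -52.1%)
```

The weak near-threshold release sites drop out of the ROI count while
the strong hotspots survive; the integrated ΔF/F falls by half. And the
exact rank test used for small-sample response comparisons:

```r
mann_whitney(1:7, c(0.5, 3.5))
#> <test_result> statistic 11; p one-sided 0.1667, two-sided 0.3333 (exact)
```

The full pipelines (striatal and retinal) run from a config via
`run_pipeline()`, or from a shell through the thin wrapper:

```sh
exec/duofluor simulate --kind striatal --out fixtures/striatal --seed 1
exec/duofluor run --config analysis.yaml
```

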