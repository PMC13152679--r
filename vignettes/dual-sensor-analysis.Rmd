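---
title: "Analysing dual-channel dopamine-sensor movies with duofluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dual-channel dopamine-sensor movies with duofluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duofluor)
```

## The measurement problem

Dopamine release in intact tissue can be imaged with optical sensors of
very different affinities. A genetically encoded GRAB-type indicator
(dissociation constant in the tens of nanomolar) responds strongly to any
release but saturates wherever extracellular dopamine is high, as it is
in the dorsal striatum. A near-infrared nanotube catecholamine sensor
(nIRCat-type, Kd in the tens of micromolar) responds weakly — in the
linear regime its fractional response is roughly three orders of
magnitude smaller at matched `dff_max` — but precisely because it does
not saturate it can resolve *where* release is strongest. Imaging both
at once gives complementary views: the high-affinity channel reports
that release happened; the low-affinity channel maps the hotspots.

`duofluor` implements the complete analysis chain for such dual-channel
time-lapse movies, together with a forward simulator that generates
movies with known ground truth so every stage can be verified without
any experimental data.

## The model pieces

**ΔF/F.** All responses are expressed as ΔF/F = (F − F0)/F0. Two
baseline conventions are supported: `prestim_mean` (F0 = mean of the
frames before the stimulus; used for evoked-release trials) and
`trial_median` (F0 = median over the whole trial; used for long
spontaneous-activity recordings, where the median is insensitive to
sparse transients). For movies F0 is computed per pixel; a nonpositive
F0 marks a dead or clipped pixel and is rejected with its location
rather than silently propagated.

**Sensor forward model.** A channel is described by equilibrium Hill
binding, ΔF/F = `dff_max · C^n / (C^n + Kd^n)` (Hill coefficient 1 by
default for both dopamine sensors; the literature constrains only the
orders of magnitude of the affinities), and by a temporal response
kernel

K(t) = (1 − e^(−t/τON)) · e^(−t/τOFF),

normalised to peak 1. The same functional form is used both to generate
synthetic transients and to fit measured ones, so kinetic-fit recovery
on synthetic data is exact by construction — passing recovery tests
shows the fitting machinery is correct, not that real sensors follow
this form. The kernel peaks at t\* = τON·log(1 + τOFF/τON), an identity
the test-suite checks numerically.

**Rise–decay fitting.** `fit_rise_decay()` fits
α(1 − e^(−x/τON))e^(−x/τOFF) + β by Levenberg–Marquardt least squares
with x measured from stimulus onset. Because the model's peak is
α·f(τON, τOFF) with f < 1, initialising α from the raw peak would bias
it low; the initial α is therefore corrected by f evaluated at the
initial time constants. The product form has shallow valleys when
τON ≈ τOFF, so the fit restarts from ±50 % log-uniform jitters of the
initial taus (three restarts, fixed internal seed) and returns the
lowest-SSE candidate. Time constants are bounded to (frame period/10,
10 × fit duration]. A constant trace is a degenerate limit (α = 0 makes
the τ gradients vanish), handled explicitly: α = 0, β = mean,
converged. Recovery performance, measured by the acceptance script at
SNR 10 (peak/noise-SD) with 100 replicates of a 30 s trace sampled at
20 Hz: median relative error ≈ 6 % (τON) and ≈ 3 % (τOFF); noiseless
traces recover all four parameters to machine precision.

**Photobleach correction.** `correct_bleach()` fits
A1·e^(−t/τ1) + A2·e^(−t/τ2) + C over the full trace and returns
x − fit + C, preserving the fitted asymptote. Initialisation comes from
log-linear fits of the early and late sections; taus are bounded to
(2 frame periods, 10 × duration]. On non-convergence the input is
returned unchanged and flagged — data are never silently altered. One
structural caveat matters: when the slow component barely decays within
the recording, (A2, τ2, C) trade off along a nearly flat direction of
the objective, so C itself is not reliably identified even though the
*subtracted curve* is. This is why the retinal pipeline normalises
before correcting (below).

**Low-pass filtering.** `lowpass()` applies a third-order Butterworth
filter at 0.68 Hz (both defaults configurable) in zero-phase
(forward–backward) mode so that event timing is not lagged — essential
for triggered averaging. The implementation builds the filter with
`signal::butter()` but performs the forward–backward pass itself with
odd-reflection padding and steady-state initial conditions, because
zero-padded filtering distorts trace edges by several percent even on a
constant input. Constants pass through exactly, the squared-magnitude
gain at the cutoff is 1/2, and at 1.47 Hz sampling the 0.68 Hz default
sits just below the 0.735 Hz Nyquist frequency and remains numerically
stable. A causal single-pass mode is available behind `zero_phase =
FALSE` for uses where physical causality matters more than timing.

**Grid hotspot mapping.** `apply_grid()` tiles the field with 8 × 8 px
squares (6 µm at the fixture's 0.75 µm pixels) anchored at the top-left
corner; partial edge squares are discarded, not padded, so all squares
have equal area. `detect_active_rois()` computes, per square, the
baseline mean and SD of its ΔF/F trace before the stimulus and the peak
inside a response window, and calls the square an active ROI when
peak > mean + k·SD with k = 2. With repeated stimulations, per-trial
peaks are averaged per square before thresholding, and baseline
statistics are averaged across trials. Baseline SD is per square, not
pooled: spatial heterogeneity of responses is the very thing the
analysis measures. The comparison is a strict inequality and involves
no division, so zero-SD (constant) squares are simply inactive and
flagged for QC, while a noiseless responding square is still detected.

**Events and triggered averages.** `detect_waves()` z-scores the
preprocessed calcium trace against its full-trace mean and SD, takes
local maxima strictly above z = 3, and resolves peaks closer than 10 s
by keeping the larger (earlier frame on ties).
`triggered_average()` centres a 60 s window on the frame *before* each
peak, drops events whose window crosses a trace boundary (counting
them), and applies identical trigger frames to every channel — this is
what lets the high-SNR calcium channel serve as the trigger for the
low-SNR nIR channel. `quantify_response()` finds the peak of the mean
trace in the 10 s windows before and after the trigger, replaces each
peak by the mean of the 3 s window centred on it, and reports the
difference. The 3 s window is clipped at the flank edges rather than
rejected (clipping is counted), so border peaks remain measurable. The
trigger sample itself belongs to neither flank.

**Statistics.** `paired_t()` is the classical paired t on differences
(at df = 2 its two-sided p has the closed form 1 − t/√(t² + 2), which
the tests verify to 10⁻¹²). `mann_whitney()` reports U for the first
sample and, for samples with nx + ny ≤ 12 and no ties, computes exact
tail probabilities by full enumeration of all C(nx+ny, nx) group
assignments; ties on small samples fall back to a seeded permutation
null (10⁵ draws), larger samples to the normal approximation with
continuity and tie corrections. Both one-sided (smaller tail) and
two-sided p are always reported and the method is labelled, because
small-sample figures in this literature are often quoted one-sided.
`linreg()` wraps ordinary least squares with R². No multiple-testing
correction is applied by default, matching common practice for these
few-comparison figure panels.

## The synthetic movie generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is verified.

A `hotspot_field()` places isotropic Gaussian release sites (normalised
to 1 at their centres) on a uniform background; a
`stimulus_protocol()` gives event frames; `simulate_concentration()`
superposes amplitude × Gaussian × normalised kernel per event and
hotspot. This linear-superposition forward model is deliberately the
simplest shape whose ground truth the grid detector can be scored
against — it makes no claim about diffusion or release physics (no PDE
modelling, no optics). `sensor_response()` applies the static Hill
transform; `render_movie()` multiplies by a double-exponential bleach
curve normalised to B(0) = 1 (so `f0_mean` is the true initial
baseline), adds i.i.d. Gaussian noise (a Poisson shot-noise mode
exists), rounds to integer detector counts, and clips to the 16-bit
range with a warning. All randomness flows from the single config seed
through a private RNG stream; identical configs give bit-identical
movies, and the user's RNG state is never touched.

### Packaged striatal fixture

`generate_striatal_fixture()` renders three stimulation trials (the
"at least three repeats" protocol) of a 64 × 64 px field at
1.47 frames/s: six hotspots of width 0.75 µm centred on grid squares,
in two amplitude tiers — strong release sites at 30–45 µM, the
concentration scale of evoked striatal release, and weak sites at
1.4–2 µM that sit a few noise-SD above threshold. Two channels are
rendered: a high-affinity channel (Kd 0.03 µM) and a low-affinity one
(Kd 30 µM). Design choices worth stating:

* *Hotspots centred on grid squares, σ = 1 px.* Compactness plus
  integer-count quantisation guarantees that neighbouring squares
  receive exactly zero signal, so the ground-truth ROI set is
  unambiguous and the noiseless fixture round-trips exactly.
* *No photobleaching in this fixture.* The evoked trials are ~60 s and
  the striatal analysis chain (by design, matching its source protocol)
  has no bleach-correction stage; including bleach would confound the
  activity criterion with drift. Bleaching is exercised by the retinal
  fixture and by dedicated rendering tests.
* *Response window brackets the kernel peak* (stimulus + τON·log(1 +
  τOFF/τON), two frames). The 30 s default window remains the function
  default, but for ROI scoring a tight window is essential — see the
  limitation below.
* *Two amplitude tiers.* In the Hill linear regime a 0.4× amplitude
  suppression scales a square's response by exactly 0.4, so only
  squares sitting within a factor 2.5 of threshold can be *de*activated
  by the suppressed ("quinpirole-like") condition; the weak tier exists
  so that condition comparison has something to show. Strong-tier
  squares stay active, which is itself faithful: a sensor criterion
  with a wide margin does not register a 0.4× change in count terms,
  only in integrated ΔF/F (≈ 50 % here).

The fixture's `truth` record carries the active-ROI set computed by
running the detection arithmetic on a noiseless rendering with the
threshold at k × the expected square-mean noise
(`noise_sd / (f0_mean · square_px)`).

### Packaged retinal fixture

`generate_wave_fixture()` renders a 16 × 16 px field for 2205 frames
(25 min) at 1.47 frames/s with double-exponential bleaching: 20
spatially global transients (kinetics of the calcium model — a wave is
a fast depolarisation) reaching 0.4 µM dopamine, near-saturating for
the calcium channel and deep in the linear regime for the nIR channel,
whose noise is set high (SD 150 counts) so single waves are barely
visible — the regime in which the calcium-triggered average is the
meaningful readout. Waves must be sparse: the z-score threshold is
defined against the full-trace SD, which dense transients inflate; with
20 waves in 25 min the expected peak z is ≈ 3.9 against the z = 3
criterion. The recorded ground-truth peak frames are the *discrete
argmax* of the sampled kernel, not the rounded continuous peak time —
the two differ by a frame whenever the true peak falls between samples.

## Pipeline stage order

The striatal chain is: per-trial ΔF/F (pre-stimulus baseline) → grid →
ROI detection (trial-averaged) → integrated response → kinetics on
active squares. Peaks are taken on unfiltered ΔF/F; the Butterworth
step belongs to the retinal chain only.

The retinal chain is: whole-field trace → ΔF/F (median of the **raw**
trace) → bleach correction of the ΔF/F trace → zero-phase low-pass →
wave detection → triggered averages → response quantification. Two
orderings deserve comment:

* *ΔF/F before filtering.* ΔF/F is an affine per-trace map and the
  zero-phase filter is linear with unit DC gain, so the two operations
  commute exactly; the order is fixed only for reproducibility.
* *ΔF/F before bleach correction.* Normalising by the median of a
  bleach-corrected trace divides by the fitted constant C, which the
  flat (A2, τ2, C) direction of the double-exponential fit can push to
  zero or below whenever the slow component is near-constant over the
  recording (and a pure double exponential has true asymptote 0). The
  median of the raw trace is always positive, and everything downstream
  (z-scoring, response differences) is invariant to the corrected
  trace's offset. Whether the original analyses corrected before or
  after normalising is not documented; this package's order is a
  deliberate well-posedness choice and is recorded in each run's
  provenance file.

`run_pipeline()` drives either chain from a YAML/JSON config or an R
list, writes every stage output as CSV/JSON plus a provenance record
(config hash, seed, stage order, package version — no timestamps, so
identical configs reproduce outputs byte for byte), and halts with the
stage name on any error. A thin command-line wrapper (`exec/duofluor`)
exposes `simulate` and `run`.

## Verification strategy, and what it does not show

The test-suite verifies three kinds of claims: *identities* (analytic
peak time, half-power gain at the Butterworth cutoff, Gaussian FWHM =
2σ√(2 ln 2), the df = 2 closed-form p, exact enumeration against base
R's `dwilcox` null); *oracle equivalence* (the vectorised ROI detector
and wave detector against plain-loop brute-force re-implementations on
hundreds of randomized instances); and *round trips* (generator →
pipeline recovery of ROI sets, wave frames to ±1 frame, kinetic and
bleach parameters). `scripts/acceptance.R` recomputes all of these from
scratch at a caller-supplied seed.

Passing these tests shows the *computations* are correct under the
generator's assumptions: Gaussian hotspots, separable kinetics, static
Hill binding, i.i.d. noise, linear superposition. Real movies violate
most of these — release sites are not Gaussian, sensors have their own
binding kinetics convolved with diffusing dopamine, noise is
photon-limited and correlated by detector readout, tissue moves. The
tests say nothing about those effects; the module boundaries
(preprocessing, mapping, kinetics, events) are where such corrections
would slot in.

## Known limitations

* **The 2-SD max criterion leaks on pure noise.** The activity rule
  compares the *maximum* of the response window against mean + 2·SD of
  baseline. For a window of n frames of pure noise the expected maximum
  is ≈ 2.2 SD at n = 44 — above threshold — and the probability of a
  false call is independent of the noise scale. Short windows and trial
  averaging reduce the per-square false-positive rate to ~0.3 % (two
  frames, three trials), but it cannot reach zero at k = 2. This is a
  property of the published criterion, not of the implementation; the
  fixture keeps hotspot squares ≥ 3.5 noise-SD above threshold so the
  truth set is recovered exactly in the typical run, and the acceptance
  script reports the agreement fraction rather than asserting
  perfection.
* **Kinetic constants near τON ≈ τOFF are weakly identified**; the
  multi-start machinery finds the global optimum but the optimum itself
  has high variance. The recovery numbers above quantify this at the
  stated sampling.
* **The bleach model has no unbleachable floor**, so its fitted
  constant is structurally unidentifiable on recordings much shorter
  than τ2 — handled by the pipeline ordering, not by the fit.
* **No motion correction, registration, or denoising** beyond the
  stated filter; no connected-component merging of adjacent active
  squares into release "sites"; no deconvolution of sensor kinetics
  from release kinetics; no wave propagation analysis.

## A worked example

```{r example, eval = FALSE}
library(duofluor)

# simulate a three-trial dual-channel evoked-release experiment
fx <- generate_striatal_fixture()

# analyse the low-affinity channel: dFF -> grid -> 2-SD ROI criterion
dff   <- lapply(fx$nir, compute_dff, baseline_spec("prestim_mean"))
grids <- lapply(dff, apply_grid, square_px = 8)
rois  <- detect_active_rois(grids, stim_frame = fx$truth$stim_frame,
                            k = 2, response_window = fx$truth$response_window)
rois
which(rois$active)          # recovered hotspot squares
fx$truth$active_nir         # generator ground truth

# kinetics of the active squares
fits <- fit_grid(rois)
fits$fits[, c("square", "tau_on", "tau_off", "converged")]

# suppressed condition
fq <- generate_striatal_fixture(amplitude_scale = 0.4)
rois_q <- detect_active_rois(lapply(lapply(fq$nir, compute_dff,
                                           baseline_spec("prestim_mean")),
                                    apply_grid, square_px = 8),
                             fq$truth$stim_frame, k = 2,
                             response_window = fq$truth$response_window)
compare_conditions(rois, rois_q)
```
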