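---
title: "Methods: models, conventions and design choices in cardiomapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in cardiomapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomapr)
```

cardiomapr quantifies whether cultured cardiomyocyte-like cells behave as
coupled excitable tissue, from three kinds of raw data: calcium-sensitive
fluorescence movies, single-frame immunofluorescence images, and
patch-clamp sweep tables. This vignette documents the underlying models,
every tunable that matters, the numerical conventions, and what the
synthetic-data module does and does not emulate.

## The frame-censored conduction-velocity bound

Let $L$ be the length of a cell cluster and $T$ the true time an
excitation wave needs to traverse it. A camera sampling at frame interval
$\Delta t$ either captures the whole traversal within one frame (no frame
boundary falls inside the traversal window) or shows an intermediate,
partially propagated frame. If the wave's start phase is uniform over the
frame clock — the natural assumption for spontaneous activity unrelated
to the camera — the single-frame probability is

$$p = \max\!\left(0,\; 1 - \frac{T}{\Delta t}\right).$$

Observing the single-frame outcome in $k$ consecutive events makes small
$p$ untenable: at confidence level $\alpha$, $p \ge \alpha^{1/k}$, hence

$$T \le \Delta t\,\bigl(1 - \alpha^{1/k}\bigr), \qquad
  CV = \frac{L}{T} \ge \frac{L}{\Delta t\,(1 - \alpha^{1/k})}.$$

Two printed forms of this bound circulate, differing in whether the root
is taken of $\alpha$ or of $1-\alpha$. Only the $\alpha^{1/k}$ form is
consistent with the event probability $p^k \ge \alpha$, and only it gives
non-degenerate bounds at $\alpha = 0.05$ (the $(1-\alpha)^{1/k}$ form
collapses toward zero for any sizeable $k$). `traversal_bound()` therefore
implements $\alpha^{1/k}$ as primary and keeps the other behind
`variant = "alt"` for comparison. A related numerical wrinkle is
documented rather than resolved: at $\Delta t = 110$ ms, $\alpha = 0.05$,
$k = 19$ the bound evaluates to 16.05 ms, whereas 14.6 ms — a figure
sometimes quoted alongside $n = 19$ — is reproduced only by $k = 21$ or
$\Delta t \approx 100$ ms. The acceptance tests assert both evaluations so
the discrepancy stays visible.

Design points:

* **Independence.** Beats within one recording and across recordings are
  treated identically as independent phase draws; beat-to-beat period
  jitter makes successive phases effectively uniform.
* **Pooling.** `estimate_from_events()` uses the *minimum* cluster length
  across events, the most conservative choice when lengths vary.
* **Refusal.** One multi-frame event falsifies the premise; the bound is
  refused (with the reason recorded) and gradient estimation is
  recommended instead. Refusal is an informative outcome: it means the
  camera resolved the propagation, so `estimate_cv()` may apply.
* **Calibration.** The bound is exact at its own boundary: simulating at
  $T = \Delta t (1-\alpha^{1/k})$ reproduces consecutive-capture rate
  $\alpha$, and with $T$ drawn uniformly the bound covers the truth in at
  least $1-\alpha$ of runs that show $k$ captures (both properties are
  tested by Monte-Carlo, 10,000–50,000 draws).

## Activation maps and gradient CV

A pixel activates at the first frame (within a beat window) where its
intensity exceeds $(1+\theta)$ times its own temporal mean. The fraction
$\theta$ defaults to 0.10 and is always recorded in the result — it is a
reporting parameter, not a hidden constant. The per-pixel reference makes
the map invariant to global intensity scaling and to static spatial
inhomogeneity; this invariance is tested exactly. The pixel mean is taken
over the full recording rather than the beat window because it is the
more stable reference across beats. Multi-beat movies are split into
windows at the midpoints between global-mean-trace peaks
(`split_beats()`); maps are numbered by beat. Never-activated pixels
carry `NA`, distinct from "activated at the re-zeroed time 0". An
optional 3×3 median prefilter (off by default) suppresses salt noise; a
ΔF/F-thresholding mode exists for recordings whose baseline drifts within
a beat window.

`estimate_cv()` fits a plane to the finite activation times and returns
the inverse gradient magnitude (µm/ms ≡ mm/s). On noiseless synthetic
plane waves it recovers the generating velocity within 10 % whenever the
wavefront spans at least ~3 frames; below that the quantisation of
activation times to the frame clock dominates, which is precisely the
regime the censored bound exists for.

## Calcium transient metrics

Traces are mean intensities over roi pixels. Detection normalises to
ΔF/F against a rolling 10th-percentile baseline (window 5 s, robust to
drift across a 30 s recording) and keeps local maxima whose topographic
prominence reaches 30 % of the trace's maximal ΔF/F.

**CaT50 convention.** "Duration at 50 % decay" is ambiguous between
peak-to-50 %-decay and full width at half maximum. The default is
peak-to-50 %-decay — the decay-kinetics reading — with `method = "fwhm"`
available. The crossing is located on the measured trace with linear
interpolation between samples, giving sub-frame precision.

**Diastolic baseline.** At ~1 Hz firing with decay constant
$\tau \approx 400$ ms the fluorescence never returns to diastole between
beats: the inter-beat floor sits $e^{-1000/408} \approx 9\,\%$ of the
amplitude above baseline, so any percentile floor overestimates the
diastolic level and biases CaT50 downward by roughly 10 %. `cat50()`
therefore estimates the baseline by extrapolating the decay to its
asymptote (monoexponential fit via `SSasymp`); `transient_table()` pools
all of a cell's aligned decay segments into one fit per cell, which is
both faster and less noisy. The rolling-percentile floor remains as the
fallback (fit failure) and as an explicit option. Because a
single-exponential decay is memoryless, measuring from the detected peak
sample leaves the analytic value $\tau \ln 2$ unchanged regardless of
where the peak falls between samples — this is what makes exact recovery
tests possible.

**Regularity.** Classification uses the *median* inter-peak interval
(robust to one missed beat): regular in (750, 1250) ms, irregular above
5000 ms, intermediate otherwise. The statistic is order-invariant by
construction. Population summaries are Gaussian mean ± SD over per-cell
mean CaT50 values.

## Morphometry and striation detection

* **Area**: pixel count × pixel area.
* **Aspect ratio**: major/minor axis of the second-moment best-fit
  ellipse, with the 1/12 per-pixel variance added so 1-pixel-wide regions
  stay finite (such regions fall back to bounding-box geometry and are
  flagged `degenerate`).
* **Circularity**: $4\pi A / P^2$ — the de-facto standard formula. The
  perimeter comes from the 8-connected contour through pixel centres,
  smoothed by a 5-vertex circular moving average (removing the staircase
  overestimate for curved outlines), plus a half-pixel Minkowski offset
  correction ($2\pi \cdot 0.5$ px) because pixel centres sit inside the
  physical boundary. On rasterised analytic shapes this lands within 3 %
  of the true value for both disks (1.0) and squares ($\pi/4$) — a pair
  that defeats single-weight chain-code estimators.
* **Fractal dimension**: box counting on the 1-pixel outline, box sizes
  in powers of 2 from 2 to a quarter of the bounding box, least-squares
  slope of $\log N$ vs $\log(1/s)$. A rasterised triadic Koch curve
  evaluates within 0.08 of $\log 4/\log 3 \approx 1.2619$.
* **Feret diameter**: maximal pairwise distance between convex-hull pixel
  centres.

**Striation.** Intensity profiles are sampled (bilinear, half-pixel
steps) along the region's major axis at ~15 minor-axis offsets,
restricted to the central 70 % of the cell to avoid end-cap edges. Each
profile is linearly detrended and Hann-windowed; the *periodograms* are
averaged across profiles (Welch) and the dominant peak within the
sarcomere band (1–3 µm, configurable) is compared with the median
spectral power inside the band. The Welch averaging is essential: for an
unstriated cell the band maximum of a single periodogram is an extreme
order statistic — several times the median for pure noise at any noise
level — whereas averaging across independent profiles shrinks it toward
the median. With the default ratio threshold of 5 the synthetic fixture
suite (20 striated, 20 unstriated rods) separates perfectly; both band
and threshold are configurable. An absolute power floor prevents
structureless (numerically zero) spectra from producing spurious calls.

Group comparison uses the Mann–Whitney U test with midranks. For group
sizes up to `exact_limit` (default 8) the two-sided p value comes from
full enumeration of all $\binom{n_1+n_2}{n_1}$ labelings of the observed
values — correct under ties, unlike classical exact tables; otherwise a
normal approximation with tie and continuity corrections is used.
Two-sided p is defined as $2\min(\text{tails})$ capped at 1. Significance
thresholds are always caller-supplied.

## Patch-clamp metrics

The depolarising step protocol (−30 mV prestep, 0 mV test step) elicits
both inward components; they are separated by a configurable time split
(default 10 ms after step onset) since a sub-10 ms transient and a
>15 ms-to-peak component do not overlap meaningfully. Currents are
baseline-subtracted against the pre-step holding level (no P/4 leak
protocol is modelled). Before extremum picking the trace is lightly
smoothed with windows matched to each component's time course (0.6 ms
fast, 5 ms slow) so the reported minimum tracks the waveform rather than
the deepest noise excursion. I–V points average the terminal window
(default 200 ms) of each step — steady-state mode — with a peak mode
available, since which convention a given lab reports is not universal.
Densities divide by the cell's capacitance (12–30 pF range in the
synthetic cohort). APD80 starts at the maximal-upstroke-velocity time
(standard convention) and ends at the linearly interpolated crossing of
80 % repolarisation; it is invariant to voltage offset and amplitude
scaling by construction.

## What the synthetic generators emulate — and what they do not

The generators produce data with the statistical structure the analyses
assume, plus exact truth records:

* `gen_wave_movie()`: planar (default) or target waves crossing a cluster
  at a set CV, sampled at Δt with the wave start phase uniform in
  $[0, \Delta t)$ — the assumption behind the capture-probability
  formula. Transients rise instantaneously and decay exponentially
  (rise time configurable), making CaT50 analytically $\tau\ln 2$.
  Additive Gaussian camera noise.
* `gen_spontaneous_traces()`: regular cells with Gaussian-jittered ~1 s
  periods, irregular cells with >5.5 s gaps; cell-to-cell spread of the
  decay constant (default SD 40 ms around 408 ms) produces the Gaussian
  CaT50 population a real culture shows. Defaults: 30 s recordings,
  20 ms sampling for single-cell traces (faster than the 110 ms
  wide-field conduction movies, as typical for higher-magnification
  recordings), amplitude equal to baseline (ΔF/F ≈ 1), noise SD 1 % of
  amplitude — a roi-averaged trace is clean.
* `gen_cell_image()`: rotated stadium-shaped footprints; striation as a
  sinusoidal modulation (depth 0.4) along the major axis, with an
  anti-aliasing guard requiring ≥ 4 pixels per period.
* `gen_ephys_sweeps()`: phenomenological alpha-function templates (fast
  peak 1.5 ms, slow peak 25 ms; the slow template is 4th-order so the
  components' feet do not overlap) and a linear-conductance outward
  component rising to a plateau — all scaling linearly with capacitance
  so densities are capacitance-invariant by construction.

Not emulated, deliberately: photon-shot (Poisson) noise is optional and
off by default; optical blur; motion artifacts; cell migration; real
membrane kinetics (activation/inactivation gating); fibroblast background
autofluorescence; dye bleaching. Passing recovery tests on this synthetic
data therefore demonstrates correctness of the *estimators under their
stated assumptions*, not robustness to every artifact of real
recordings. Camera bit depth, magnification and field size are
configurable, not inferred defaults.

## Numerical conventions and problem sizes

Frame indices are 1-based in R; activation times are reported re-zeroed
to the earliest activated pixel in ms; pixel coordinates are (row, col)
with row 1 at top. All threshold crossings interpolate linearly between
samples. `mm/s` equals `µm/ms`, so CV arithmetic needs no unit factors.
Readers refuse to guess physical units; TIFF output quantises to 16-bit
integers (lossless for integer-valued stacks). Every generator accepts a
seed and restores the caller's RNG state, so identical seeds give
bit-identical artifacts.

The shipped validation uses problem sizes chosen to make the statistical
checks sharp while keeping the whole suite fast on one CPU: 50,000 phase
draws for the capture-probability oracle, 10,000 for bound calibration
and coverage, 1000 single-beat movies for the event-frequency check, 20
seeds for gradient-CV recovery, 50 seeds × 26 cells for CaT50 recovery,
40 cells for the striation fixture suite, and full enumeration of all
Mann–Whitney splits to $n_1+n_2=12$.

## Known limitations

* The censored bound assumes the activation map's single-frame calls are
  correct; heavy noise with a low θ could split a true single-frame event
  into two frames and silently weaken the bound (the refusal path errs
  conservative).
* The asymptote baseline estimator assumes a monotone, roughly
  exponential decay; markedly biphasic decays will push it to the
  percentile fallback.
* Box-counting dimension on small regions (outline < ~8 boxes at the
  largest scale) is returned as `NA` rather than extrapolated.
* The ephys module analyses templates of currents, not gating models; it
  cannot be used to fit kinetics, only amplitudes, densities and
  durations.
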