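# cardiomapr

Functional characterization of stem-cell-derived cardiomyocytes from
optical-mapping movies, immunofluorescence images and patch-clamp sweeps —
an R toolkit for labs assessing whether differentiated cells behave like
coupled, excitable cardiac tissue.

The package covers five analyses that together make that call:

1. **Calcium transient metrics.** Per-cell fluorescence traces are
   normalised to ΔF/F against a rolling-percentile baseline; peaks give
   the spontaneous excitation interval *T*, and the **CaT50** (time from
   transient peak to 50 % decay of the amplitude above diastolic
   baseline, linearly interpolated) quantifies decay kinetics. Cells are
   classed *regular* (median interval in 750–1250 ms), *irregular*
   (median > 5 s) or *intermediate*.

2. **Adaptive-threshold activation mapping.** A pixel activates at the
   first frame where its intensity exceeds its own temporal mean by a
   fraction θ: `I > (1 + θ) · mean_t(I)`. Because every pixel is measured
   against itself, the map is immune to uneven illumination and dye
   loading, unlike a global threshold. Activation-time gradients give
   conduction velocity (CV) when the wavefront spans several frames.

3. **Frame-censored CV lower bound.** When propagation across a cluster
   of length *L* is faster than the camera (traversal time *T* < frame
   interval Δt), the wavefront is usually captured inside a single frame.
   With the wave phase uniform over the frame clock,
   `p = max(0, 1 − T/Δt)`. Observing *k* consecutive single-frame events
   at confidence level α implies

   ```
   T ≤ Δt (1 − α^(1/k))        and so        CV = L/T ≥ L / [Δt (1 − α^(1/k))]
   ```

   turning an apparent camera limitation into a quantitative bound on
   electrical coupling. A Monte-Carlo oracle (`mc_validate()`) verifies
   the closed form, and `estimate_from_events()` refuses the bound the
   moment any multi-frame event is observed.

4. **Morphometry and striation.** Area, ellipse-fit aspect ratio,
   circularity `4πA/P²`, box-counting fractal dimension of the outline,
   and Feret diameter per segmented cell; sarcomeric striation is called
   from the dominant 1–3 µm spectral peak of intensity profiles along the
   cell's major axis (periodograms averaged across profiles). Groups are
   compared with an exact-enumeration Mann–Whitney U test.

5. **Patch-clamp metrics.** Fast/slow inward peak currents from the
   −30 mV-prestep depolarising protocol, capacitance-normalised current
   densities (pA/pF), steady-state I–V curves from step families, and
   APD80 from current-clamp traces (maximal-upstroke-velocity start,
   80 % repolarisation crossing).

Every analysis is exercised end-to-end against a synthetic-data module
(`gen_wave_movie()`, `gen_spontaneous_traces()`, `gen_cell_image()`,
`gen_ephys_sweeps()`, `gen_ap_trace()`) that records exact ground truth
for recovery testing.

## Worked example

```r
library(cardiomapr)
res <- run_demo_pipeline("demo_out", seed = 1)
res$bound
#> <cv_bound> dt = 110 ms, k = 19, alpha = 0.05 (primary)
#>   T <= 16.05 ms; CV > 19.9 mm/s (L = 319.531 um)
res$cat50_summary
#> # A tibble: 1 x 3
#>   mean_ms sd_ms     n
#>     <dbl> <dbl> <int>
#> 1    296.  28.1    26
```

The demo simulates a 300 µm cluster conducting at 100 mm/s, imaged at
Δt = 110 ms for 19 spontaneous beats. All 19 propagation events land
within single frames for this seed, so the censored bound applies with
k = 19: traversal time below 16.05 ms, hence CV above ~20 mm/s — the
method recovers a correct (and deliberately conservative) bound on the
simulated 100 mm/s truth. The transient population (26 regular cells,
decay constant 408 ms → analytic CaT50 = 408·ln 2 ≈ 283 ms) is recovered
as 296 ± 28 ms on this seed. `res$morph_comparison` contrasts rod-shaped
against rounded cells: aspect ratio, circularity and Feret differ at
p < 0.01 (exact Mann–Whitney), area and fractal dimension do not —
matching how the two generated phenotypes were constructed. With faster
conduction or unlucky phases a multi-frame event can occur, in which case
the bound is refused with an explanatory message rather than reported;
that refusal is part of the method's contract.

Each result type has a plot: `autoplot()` on activation maps, space–time
plots and transient metrics; `plot_iv_curve()` and
`plot_cat50_scatter()` for the tabular results.

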