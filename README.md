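# atvseg

Does denoising a CT scan before segmenting it make the contours better?
`atvseg` is an R toolkit for studying exactly that question in radiotherapy
planning, where organs at risk (heart, lungs, esophagus, spinal cord, liver)
must be delineated on non-contrast CT whose soft-tissue boundaries are often
buried in noise. The package provides:

* an **anisotropic total-variation (ATV) denoiser** for CT slices, with an
  adaptive steepest-descent optimizer,
* a **2D noise-power-spectrum (NPS)** analyzer with radial profiling and
  peak/mean spatial-frequency summaries,
* **contour-agreement statistics**: the Dice similarity coefficient and the
  paired Wilcoxon signed-rank test, with table-style summaries,
* a **seeded synthetic thorax phantom** with ground-truth organ masks, so the
  whole chain is testable without patient data, and
* an end-to-end **denoise → segment → evaluate pipeline** in which a fixed
  intensity-window segmenter plays the role of the (external) segmentation
  model, so the only varying factor between arms is the denoising step.

Volumes are read/written as single-frame CT DICOM series; masks as NIfTI
rasters with a JSON sidecar.

## The model

The denoiser minimizes the weighted total variation of each axial slice

```
R(V) = Σ_j w_j D(V_j)
D(V(x,y)) = sqrt( (V(x,y) − V(x−1,y))² + (V(x,y) − V(x,y−1))² )
w_j  = Σ_{m ∈ N_j} exp[ −((V_j − V_m)/δ)² ]
```

where `N_j` are the four first-order neighbors and δ is set to the 80 %
point of the cumulative distribution of the per-pixel gradient magnitude.
`w_j` is the conduction coefficient familiar from anisotropic diffusion:
neighbors across a high-contrast edge contribute almost nothing, so edges
are preserved while low-contrast noise is smoothed. Optimization is
normalized steepest descent

```
V^{t+1} = V^t − λ ∇R(V^t) / |∇R(V^t)|,   λ ∝ γ · sqrt(Σ_j V_j²)
```

for 20 iterations, where γ starts at 1.0 and is multiplied by 0.8 whenever
the objective increases. Segmentation agreement is scored with
`DSC = 2|A∩B| / (|A| + |B|)` (0.80 is flagged as the conventional
acceptability bound) and method differences are tested with a two-sided
paired Wilcoxon signed-rank test (exact by enumeration for small n).

## Worked example

```r
library(atvseg)

bundle <- build_phantom(default_thorax_spec(sigma = 40, seed = 42))
report <- run_pipeline(bundle)
report
#> # A tibble: 6 × 3
#>   organ          raw denoised
#>   <chr>        <dbl>    <dbl>
#> 1 lung_right  0.955    0.982
#> 2 lung_left   0.949    0.981
#> 3 heart       0        0.391
#> 4 esophagus   0        0.0102
#> 5 liver       0.0514   0.790
#> 6 spinal_cord 0        0
#> NPS (liver ROIs):
#> # A tibble: 2 × 5
#>   arm      peak_frequency peak_value mean_frequency n_bins
#>   <chr>             <dbl>      <dbl>          <dbl>  <int>
#> 1 raw               0.383      1768.          0.385     11
#> 2 denoised          0.147       318.          0.223     11
```

Reading: at σ = 40 HU the raw window segmenter only finds the
high-contrast lungs; after ATV denoising the liver (a 25 HU contrast
organ) jumps from DSC 0.05 to 0.79, while the lungs stay excellent. The
liver-ROI noise spectrum confirms the mechanism: the NPS peak drops
(1768 → 318 HU² mm²) and both the peak and the power-weighted mean spatial
frequency shift to lower values (0.385 → 0.223 mm⁻¹) — the noise that
remains is weaker and smoother. Per-slice optimizer diagnostics are
available as tidy tibbles:

```r
res <- denoise_slice(withr::with_seed(42, matrix(50 + rnorm(64^2, sd = 20), 64, 64)))
glance(res$state)
#> # A tibble: 1 × 7
#>   iterations delta objective_initial objective_final objective_ratio ...
#> 1         20  49.2           394593.         122267.           0.310
```

`autoplot()` methods exist for denoiser states, NPS profiles and pipeline
reports; `tidy()`/`glance()` for all result objects; `dsc_table()` builds
per-organ two-method comparison tables with Wilcoxon p-values.

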