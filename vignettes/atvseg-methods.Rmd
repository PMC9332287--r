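---
title: "Methods: ATV denoising, NPS analysis and segmentation evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ATV denoising, NPS analysis and segmentation evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atvseg)
```

`atvseg` studies a simple but practically important question from
radiotherapy planning: when a fixed segmentation procedure is fed a denoised
CT volume instead of the raw one, do the resulting organ contours agree
better with the ground truth? This vignette documents the models the package
implements, the conventions it fixes where the underlying mathematics leaves
choices open, and what its synthetic experiments can and cannot show.

## The ATV objective

Each axial slice `V` is treated as a 2D grid of Hounsfield units. The
denoiser minimizes the anisotropically weighted total variation

$$R(V) = \sum_j w_j\, D(V_j), \qquad
D(V(x,y)) = \sqrt{(V(x,y)-V(x-1,y))^2 + (V(x,y)-V(x,y-1))^2 + \epsilon^2},$$

$$w_j = \sum_{m \in N_j} \exp\!\left[-\left(\frac{V_j - V_m}{\delta}\right)^2\right],$$

with `N_j` the in-bounds 4-neighborhood (4 terms for interior pixels, 3 on
edges, 2 at corners). The weight is the conduction coefficient of
anisotropic diffusion: where a pixel sits against a strong edge, the
corresponding exponential is tiny and the local TV penalty is largely
switched off, so minimization smooths low-contrast noise while leaving
high-contrast structure alone.

Conventions fixed by the package:

* **Coordinates.** `(x, y) = (column, row)`; backward differences; the
  border is *replicated* (`V(-1, y) := V(0, y)`), so boundary difference
  terms vanish identically.
* **Differentiability guard.** The square root in `D` is regularized by
  `sqrt_epsilon` (default `1e-3` HU). This makes the gradient of a constant
  slice exactly zero instead of 0/0 and is far below CT quantization, so it
  never affects results materially.
* **Edge scale δ.** Estimated *once from the input slice* as the
  `delta_quantile` (default 0.80) point of the empirical distribution of
  `D` over all pixels, with linear interpolation between order statistics
  (type-7 quantile). A floor of `1e-6` HU guards constant slices. Estimating
  δ once treats it as a property of the acquired image, not of the iterate;
  re-estimating per iteration would progressively shrink δ as noise is
  removed and over-sharpen the weights.
* **Frozen-weight gradient.** `w` depends on `V`, but the analytic gradient
  treats it as a constant (the lagged-diffusivity convention of the
  anisotropic-diffusion literature). The finite-difference oracle in the
  test suite freezes `w` identically; agreement is required to a relative
  1e-4 and observed near 1e-9. Weights are refreshed from the current
  iterate each iteration by default (`weight_refresh = "per_iteration"`);
  `"fixed_initial"` keeps the input image's weights, which is also
  defensible and provided because the choice is genuinely open.

## The optimizer and the step size

Minimization is normalized steepest descent,
$V^{t+1} = V^t - \lambda\, \nabla R(V^t)/|\nabla R(V^t)|$, run for
`iterations = 20` updates. γ starts at `gamma_init = 1.0` and is multiplied
by `gamma_decay = 0.8` each time the objective *increased* over the last
update (the step itself is kept); this anneals the step length when the
iterate starts oscillating around a valley. The loop stops early if the
gradient norm is exactly zero (constant input).

Because the gradient is normalized to unit length, λ is the Euclidean norm
of the whole update vector. The raw prescription
$\lambda = \gamma\sqrt{\sum_j V_j^2}$ therefore scales with *image size*:
for a 64×64 patch around 50 HU it is ≈ 3400 HU per iteration, and for a
512×512 CT slice it would be two orders of magnitude larger still — the
iterate overshoots any plausible minimizer and, measured on a 0/300 HU step
phantom, *increases* within-region variance ten-fold in 20 iterations. The
package therefore normalizes the step per pixel by default
(`lambda_norm = "rms"`):

$$\lambda = \gamma\,\sqrt{\tfrac{1}{n}\sum_j V_j^2},$$

i.e. γ times the root-mean-square pixel value, which makes the update
magnitude independent of grid size and of the right order for HU-scaled
images. With this default, on the package's reference experiment (64×64
uniform 50 HU patch, white noise σ = 20 HU, seed 42, default
configuration) the objective falls to 0.31 of its initial value and the
pixel variance to 0.17, while on the step phantom the 300 HU edge height is
preserved to 0.1 % and within-region variance drops by 98 %. The
unnormalized form remains available as `lambda_norm = "sum"`, and a global
`lambda_scale` multiplier is exposed; both exist so the raw prescription can
be reproduced and studied rather than silently corrected.

Two properties of the scheme are worth knowing:

* On a *noiseless* piecewise-constant image the weights cannot switch off
  edge terms completely — `w_j` is a single scalar per pixel, summed over
  all four neighbors, so an edge pixel still carries weight from its
  same-region neighbors. The denoiser consequently erodes edges slightly
  (classical TV shrinkage) even when there is no noise to remove. Organs
  separated by hundreds of HU are unaffected at segmentation level;
  intensity windows only a few HU wide are sensitive to it.
* The recorded γ sequence is non-increasing, each decay is by the factor
  0.8 exactly, and decays coincide one-to-one with recorded objective
  increases — this is asserted by the test suite as an invariant.

## Noise power spectrum

The NPS module follows the standard uniform-region ensemble estimator: square
ROIs inside a homogeneous organ, replicated over adjacent slices (the default
protocol uses three ROIs over five consecutive slices, 15 patches). Each
patch is detrended by least-squares removal of a 2D polynomial (order 2 by
default, configurable 0–2) and the spectrum is

$$\mathrm{NPS}(f_x, f_y) = \frac{d_x d_y}{N^2}
\left\langle \left| \mathrm{DFT}_{2D}(\text{residual}) \right|^2 \right\rangle,$$

zero-frequency centered, axes in mm⁻¹ with the Nyquist frequency
`1/(2 dx)` at the extreme. Integrated over both axes this recovers the
residual pixel variance (Parseval); the test suite checks the integral to
within 5 % on 100 seeded white-noise patches. No window/taper is applied —
the plain TG-233-style baseline. The radial profile averages the 2D NPS
over annuli of width equal to the smaller axis increment by default,
*excluding the DC sample*, which carries detrending residue rather than
noise; `peak_frequency` is the center of the maximal bin and
`mean_frequency` the power-weighted mean — the two summaries used to
compare textures before and after denoising.

## Contour agreement statistics

`dice()` implements `DSC = 2|A∩B|/(|A|+|B|)`. Two empty masks are an
*error*, not 1.0: the ratio is 0/0, and silently reporting success would
mask upstream segmentation failures. `paired_wilcoxon()` drops zero
differences (the classical convention), midranks ties, takes the smaller
signed-rank sum as the statistic, and computes the two-sided p exactly for
up to `exact_threshold = 25` effective pairs via the shift-convolution
distribution of the rank sum — mathematically identical to enumerating all
2ⁿ sign assignments, which the test suite does literally for n ≤ 10.
Beyond the threshold a normal approximation with midrank (tie) variance and
a 0.5 continuity correction is used; on tie-free data the exact path
reproduces `stats::wilcox.test`'s exact p, and the approximate path its
tie-corrected p. All p-values are two-sided. `dsc_table()` aggregates
per-case DSC values of two methods into per-organ means, Wilcoxon p-values
and a conventional DSC ≥ 0.80 acceptability flag.

## The synthetic phantom and the reference segmenter

No patient data ship with the package; every experiment runs on a seeded
phantom. The `thorax-default` preset is a 128 × 128 × 10 volume at 1 × 1 mm
spacing and 3 mm slice thickness emulating a non-contrast planning CT:
soft-tissue background (30 HU), two lungs (−680 / −740 HU — both "≈ −700",
split so one intensity window can address each), heart (45 HU), liver
(55 HU), a deliberately low-contrast esophagus (35 HU, within 10 HU of
background, mimicking the clinical difficulty of that organ), and a spinal
cord (40 HU) inside a +700 HU vertebral ring (painted, but not exported as
an organ mask). Organs are ellipsoids painted in priority order — later
structures carve earlier ones, and each mask is exactly the painted voxel
set, so ground truth is analytic. Noise is additive white Gaussian of
configurable σ, or Gaussian-kernel-correlated noise (unit-L2 kernel, so the
variance stays σ²) for a more CT-like texture. Identical spec + seed gives
bit-identical bundles.

What the phantom does *not* emulate: beam hardening, scatter, streaks,
anatomical texture, partial-volume edges, or the spatially varying,
radially correlated noise of filtered back-projection. Passing tests on the
phantom therefore demonstrate correctness of the implementation and the
*direction* of the denoising effect on segmentation, not clinical
performance on patient scans.

The segmenter deliberately is not a learned model: per organ it thresholds
an HU window, keeps the largest 26-connected component, and applies 3D
morphological closing (radius 1 voxel by default). What matters for the
study design is that it is *fixed and deterministic*, so the two pipeline
arms differ only in denoising. Its default windows bracket each preset
organ's mean without touching the neighbors' means, which recovers the
noiseless phantom exactly (DSC 1 for all six organs, asserted in the test
suite). Connected components and closing are computed by vectorized label
propagation / shift-based morphology implemented in the package, since no
installed package offered 3D variants.

## Problem sizes and determinism

The shipped experiments are desk-scale by design: 64×64 patches for the
optimizer reference run, 32×32 × 100 patches for the Parseval check, 20
seeds × 10 patches for the frequency-shift experiment, and 20 seeded
128 × 128 × 10 phantoms at σ = 40 HU for the liver comparison (restricted
to the liver so the whole suite stays in the minutes range; one full
six-organ run backs the determinism and structural checks). Everything is
driven by explicit seeds through `withr::with_seed`, and the pipeline is
bit-reproducible: two runs with equal seeds produce identical reports,
segmentations and diagnostics.

## Known limitations

* 2D slice-wise denoising only; the objective is defined on `(x, y)` and
  no 3D TV variant is provided.
* The DICOM codec reads/writes single-frame CT objects in Explicit VR
  Little Endian only — sufficient for the package's own series and for
  plain scanner exports of that form, but not a general DICOM toolkit
  (no sequences, no compressed transfer syntaxes, no RT-structure
  polygons; masks travel as NIfTI rasters instead).
* The intensity-window segmenter is a stand-in: absolute DSC values it
  produces are not comparable to a modern learned segmenter's; only
  *within-experiment contrasts* (raw vs denoised under an identical
  segmenter) are meaningful.
* On noiseless images the denoiser slightly erodes edges (see above); with
  very narrow HU windows this can move a low-contrast organ's boundary by
  a pixel even without noise.
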