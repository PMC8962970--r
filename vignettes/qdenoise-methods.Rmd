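---
title: "Denoising quantum-dot fluorescence images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising quantum-dot fluorescence images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Porous-silicon (PSi) array biosensors read out analyte concentration
optically: quantum dots bound to target DNA inside the pores fluoresce
under UV excitation, and the *average gray level* (AGL) of the
fluorescence micrograph is proportional to the number of bound quantum
dots, hence to concentration.  The disordered nanostructure of the PSi
surface multiplies the clean signal by speckle-like noise.  The noise is
well described as multiplicative gamma noise,

$$F = U \odot N, \qquad N \sim \Gamma(L, L), \quad
  E(N) = 1, \quad \mathrm{Var}(N) = 1/L = v,$$

so the *expected* gray level is untouched but individual acquisitions
scatter, 8-bit clipping truncates the heavy right tail, and the gray
difference between pre- and post-reaction images — the assay readout —
becomes noisy.  The package implements a denoiser built specifically to
restore the AGL rather than merely to look smooth, together with the
simulator, metrics, noise-type identification and the quantitation chain
(calibration line and 3σ/slope detection limit) needed to evaluate it.

## Pipeline

`denoise()` chains four stages:

1. **Noise-level estimation.** The coefficient of variation δ is the mean
   of s/μ over P = 8 non-overlapping 20×20 homogeneous windows, selected
   by ranking windows on the energy of an eight-direction Laplacian
   high-pass map.  (One published formula prints σ²/μ while the prose
   defines the ratio of standard deviation to mean; the standard CV is
   the default and the σ²/μ variant is kept behind `variant = "var"`.)
2. **Non-local-means reference.** A 21×21-search, 7×7-patch NLM smooth
   `Ĩ` with weights $\exp(-\lVert P_i - P_k\rVert^2/h^2)$.  `h` is set
   automatically to `nlm_h_factor × δ × AGL` (default factor 20): strong
   smoothing is wanted here because `Ĩ` serves as a *compression target*,
   and weaker smoothing leaves the reference biased ~0.3–0.4 gray below
   the true level on skewed gamma noise (patch similarity favours the
   dense low side of the distribution).
3. **Gray-value compression (GVC).** Pixels step toward the reference by
   γ·I/10 per iteration, γ = exp(−I/Ĩ) recomputed each iteration against
   the fixed reference; above-reference pixels step down, below-reference
   pixels step up.  The iteration budget comes from a calibrated monotone
   curve δ → k (below).
4. **Cosine-distance nonlocal anisotropic diffusion (CNLAD).** Per
   iteration: the per-pixel statistic q is the spatially weighted
   (fixed 7×7 ring kernel G, centre 1, rings 0.8/0.6/0.4) mean cosine
   similarity between the centred 3×3 patch and the 49 patch positions of
   its 9×9 search box; the threshold T is the image mean of q; the
   diffusion coefficient is c = 1/(1 + (q − T)²); a type-2 fuzzy
   membership U gates the explicit 4-neighbour step
   $$I^{+} = I + \Delta t\,\tfrac{1-U}{4}\sum_{n} c_n (I_n - I)$$
   with zero-flux boundaries.  All fields are recomputed from the current
   image every iteration, and the loop stops early once the mean absolute
   update falls below `stop_tol`.

The cosine similarity uses the standard normalized form
⟨a,b⟩/(‖a‖‖b‖); the no-square-root variant that appears in one printed
formula is available via `exact_cosine = FALSE` for comparison, since the
surrounding text defines the statistic as the cosine of the angle between
the two patch vectors.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `nlm_search`, `nlm_patch` | 21, 7 | px | NLM geometry |
| `nlm_h_factor` | 20 | × noise sd | smoothing strength of the reference |
| `gvc_step_divisor` | 10 | – | compression step γ·I/divisor |
| `cv_P`, `cv_window` | 8, 20 | –, px | CV estimation windows |
| `cnlad_search`, `cnlad_patch` | 9, 3 | px | variation-field geometry |
| `dt` | 0.2 | – | explicit time step (stability needs ≤ 0.25) |
| `n_iter`, `stop_tol` | 220, 1.5e-4 | –, gray | diffusion budget / early stop |
| `gate_delta_u`, `gate_delta_l` | 0.2, 0.1 | gray (at `gate_scale = 1`) | type-2 membership widths |
| `gate_k` | 2 | – | mean-of-k-middle order |
| `gate_scale` | 1 | – | intensity divisor for the gate |

`n_iter` and `stop_tol` were chosen by minimizing the v = 0.5 benchmark
RMSE (the published study does not state its iteration count); `dt`
keeps the conventional 0.2.

**The gate scale.** The membership widths 0.2/0.1 need an intensity
scale.  Evaluated on a [0, 1]-normalized image they are far wider than
any post-compression residual (~0.008 of full scale), the membership is
≈1 everywhere, the factor (1 − U) is ~10⁻³, and diffusion stalls —
the pipeline then cannot reproduce the published AGL/SSIM behaviour.
Evaluated on the raw gray scale the gate closes exactly when a pixel is
within a few tenths of a gray of its neighbourhood mean-of-k-middle,
which is what the published error magnitudes imply.  The package
therefore defaults to `gate_scale = 1` (raw); `gate_scale = 255` keeps
the normalized variant available.

## GVC calibration

The δ → k curve ships as `extdata/gvc_calibration.csv` and is
regenerated by `calibrate_gvc()`: constant images at grays 50 and 60,
variances 0.1–0.9, 5 seeds each; for each image the smallest k is found
at which compression is *complete*, then an isotonic curve is fitted
through (δ, k) and anchored at (0, 0).

"Complete" pairs two criteria: the histogram peak of the compressed
image lies within ±0.5 gray of the true level, **and** the mean absolute
distance to the reference has reached the compression oscillation floor
(`floor_tol = 1.2` gray — a converged pixel keeps stepping by
γI/10 ≈ 1.8 gray around the reference, so the mean distance cannot fall
much below ~1).  The peak criterion alone is met within a handful of
iterations, long before the skewed bright tail of the gamma distribution
has been compressed; stopping there leaves the downstream AGL 2–4 gray
high at v ≥ 0.5, contradicting the near-delta post-compression
histograms the method is designed to produce.  The distance criterion
supplies the missing notion of "the histogram has actually
concentrated".

Two numerical details of the peak:

* the peak is the modal integer bin refined by parabolic interpolation
  through its two neighbours — an un-interpolated integer mode has one
  gray of resolution and cannot support a ±0.5 criterion;
* at 256×256 the peak of one realization carries irreducible sampling
  scatter (the pixel-mean standard error alone is 0.18 gray at v = 0.9),
  so the calibration acceptance check is applied to the *mean* peak over
  the five replicate seeds of each (gray, variance) condition.  All 18
  condition means land within the band (worst deviation 0.48 gray).

## What the synthetic data emulate — and what they do not

`make_noise_dataset()` builds the ten-family labelled noise set
(constant grays 30–100, five intensities per family, 2000 images,
1700/300 split) used by the classifier; `synth_array_image()` draws
circular PSi units whose red-channel gray is `intercept + gain ×
concentration`, multiplied by gamma noise, with the ground-truth layout
attached.  These fixtures reproduce the *statistical* structure the
method addresses (multiplicative mean-one noise, linear gray–
concentration response, dark background) but none of the optics of real
micrographs: no point-spread function, no illumination gradients or
vignetting, no sensor Poisson–Gaussian mixture, no inter-wafer
variability, and perfectly circular units.  Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model,
not performance on any particular microscope.  The published real-image
calibration coefficients (slopes 9.21 and 17.62, σ = 0.27) are consumed
as printed constants in the detection-limit arithmetic; they are not
re-derivable without the original micrographs.

The classifier behind `train_classifier()` is a single-hidden-layer
softmax network over the 256-bin histogram augmented with moment
summaries, not a deep residual network; it is the component this
toolchain can support, the module's contract (histogram features in,
ten-class posterior out, ≥95% held-out accuracy) is unchanged, and the
denoiser does not depend on it.

## Numerical choices and degenerate inputs

* Borders: reflect (half-sample symmetric) padding everywhere;
  zero-flux mirrored boundaries in the diffusion step.
* Cosine similarity of two all-zero patches is 1 (identical), of one
  all-zero patch 0.
* A noiseless image has δ = 0, maps to k = 0 compression iterations, its
  variation field is identically 1 = T, and the gate is 1 everywhere, so
  the pipeline is an exact fixed point on clean constant images.
* δ above the calibrated range clamps to the largest calibrated k with a
  warning.
* Window selection breaks energy ties in row-major order; if stride-1
  greedy selection fragments the plane it falls back to the disjoint
  tiling grid, so the requested window count is always achievable when
  capacity allows.
* All randomness flows through explicit seeds; every simulation is
  bit-reproducible.

## Problem sizes

Simulation experiments use 256×256 images, 10 noise realizations per
variance for pipeline metrics, 5 seeds per condition for calibration
checks, and 5 repeated images per concentration for the biosensor
recovery study — sizes at which the Monte-Carlo error is a small
fraction of every tolerance asserted in the tests.

## Known limitations

* The output is pinned to the 21×21 NLM reference, whose statistical
  floor on a constant image is σ/21 ≈ 2.26 gray at v = 0.9; the gated
  diffusion grinds this smooth error field down to ≈ 2.0–2.1 gray RMSE
  and then equilibrates.  Published RMSE values below this floor at high
  variance are not reachable by any estimator tied to 21×21 local
  averages; AGL and SSIM behaviour are reproduced throughout.
* The type-2 gate treats strong step edges as "noise" (large departure
  from the window mean-of-k-middle), so real edges blur over long
  diffusion runs; quantitation on array images therefore measures unit
  gray over masks eroded well inside each unit.
* The gate scale, calibration completion rule and sub-bin peak are the
  package's own resolutions of genuinely under-specified design points;
  each keeps the alternative available behind a flag or argument.
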