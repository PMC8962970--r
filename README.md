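# qdenoise

Denoising and gray-value quantitation for quantum-dot fluorescence images
from porous-silicon (PSi) array biosensors.

PSi biosensors read target concentration through the average gray level
(AGL) of quantum-dot fluorescence: the brighter a sensor unit, the more
labeled probe has bound. The rough nanostructured surface corrupts these
micrographs with speckle-like **multiplicative gamma noise**, `F = U ⊙ N`
with `N ~ Γ(L, L)` (mean 1, variance `v = 1/L`), which distorts the
measured AGL and degrades the detection limit. Generic denoisers restore
texture but shift the mean gray; this package implements a pipeline whose
objective is AGL fidelity:

1. **Noise level estimation** — coefficient of variation `δ = mean(sᵢ/μᵢ)`
   over 8 homogeneous 20×20 windows found by an eight-direction Laplacian
   energy ranking.
2. **Gray-value compression (GVC)** — iterative shrinkage of each pixel
   toward a 21×21/7×7 non-local-means reference `Ĩ`, step `γ·I/10` with
   `γ = exp(−I/Ĩ)`; the iteration budget comes from a calibrated `δ → k`
   curve shipped with the package.
3. **Cosine-distance nonlocal anisotropic diffusion (CNLAD)** — explicit
   diffusion `I⁺ = I + Δt·(1−U)/4 · Σ cₙ(Iₙ − I)` whose edge statistic `q`
   is the spatially weighted mean cosine similarity between each pixel's
   3×3 patch and the 49 patches of its 9×9 search box, with
   `c(q) = 1/(1+(q−T)²)`, `T = mean(q)`, gated by a type-2 fuzzy
   membership `U` (Gaussian memberships σ = 0.2/0.1 around the 3×3
   mean-of-k-middle).
4. **Quantitation** — unit segmentation (Otsu + morphology), ΔAGL vs
   concentration by ordinary least squares, and the detection limit
   `LOD = 3σ/slope` in pM.

It also ships the noise simulator (ten labeled noise families), a
noise-type classifier over histogram features, and AGL/RMSE/SSIM
benchmarking over the variance grid 0.1–0.9.

## Worked example

```r
library(qdenoise)

clean <- matrix(50, 256, 256)
noisy <- apply_multiplicative_noise(clean, variance = 0.5, seed = 7)
c(agl(noisy), rmse(noisy, clean), ssim(noisy, clean))
#> 49.80  35.06  0.050

res <- denoise(noisy)
res
#> CNLAD denoising result (256x256)
#>   coefficient of variation: 0.6726
#>   GVC iterations: 298  (NLM h = 669.9)
#>   diffusion iterations: 200
#>   AGL in: 49.799  out: 49.704
c(agl(res$image), rmse(res$image, clean), ssim(res$image, clean))
#> 49.70  1.53  0.995
```

The raw image's mean gray is right on average but its per-pixel error is
huge (RMSE ≈ 50·√0.5 ≈ 35); after denoising the RMSE drops ~23× and the
structural similarity rises from 0.05 to 0.995 while the AGL stays within
0.3 gray of the truth — the property the biosensor readout depends on.

Calibration arithmetic:

```r
x <- c(0.1, 0.25, 0.5, 1)                     # nM
fit <- concentration_fit(x, 17.62 * x + 0.837, sigma = 0.27)
fit
#> Calibration: dAGL = 17.620 * conc + 0.837   (R^2 = 1.0000)
#>   sigma = 0.270 gray  ->  LOD = 3*sigma/slope = 46.0 pM
detection_limit(0.27, 9.21)                   # pre-denoising slope
#> 87.9
```

A steeper post-denoising calibration slope halves the detection limit
(87.9 → 46.0 pM) at the same blank-measurement σ.

A thin command-line wrapper lives at `inst/cli/qdenoise`
(`simulate`, `denoise`, `gvc`, `benchmark`, `biosensor`, `biosensor-fit`,
`calibrate-gvc`, `classify`).

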