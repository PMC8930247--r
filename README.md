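# knlmeans

Speckle denoising for 2-D grayscale ultrasound images in R:
**non-local means** (NL-Means) patch filtering, a **gradient-augmented**
variant, and **KNL-Means** — NL-Means preceded by a K-means
classification of pixels so that averaging candidates are drawn only
from the same tissue class, which preserves edges and detail. The
package is aimed at researchers evaluating speckle filters on
synthetic ground truth, and ships everything that evaluation needs: a
kidney-like piecewise-constant phantom generator with a multiplicative
speckle model, a robust image noise estimator that sets the filter
bandwidth, PSNR/MSE metrics, a seeded multi-method benchmark harness,
a command-line front end, and the renal Doppler resistive index used
as the hemodynamic endpoint in kidney studies.

## The method

NL-Means estimates each pixel as a weighted average over candidates:

    S(w(i)) = Σ_j T(i,j) w(j)
    T(i,j)  = exp(−d(i,j) / a²h²) / K(i)
    d(i,j)  = Σ_l G(l) (w(i+l) − w(j+l))²

with `G` a Gaussian kernel over patch offsets (normalized to sum 1),
`h` the bandwidth, and `K(i)` the normalizer. The bandwidth defaults
to `λ·σ̂` with `σ̂` estimated from the image itself by
median-absolute-deviation-scaled Laplacian pseudo-residuals. The
gradient-augmented variant multiplies each per-offset intensity
difference by the corresponding difference of gradient magnitudes
inside the square, which suppresses averaging with detail-bearing
patches. KNL-Means first clusters pixels by K-means on local
(patch mean, patch std) features and restricts the candidate set of
every pixel to its own class; with `K = 1` it reduces bit-identically
to plain NL-Means.

## Worked example

```r
library(knlmeans)

clean <- make_phantom(phantom_spec(128, 128, c(0.2, 0.5, 0.8), seed = 1))
noisy <- add_speckle(clean, speckle_params(sigma = 0.2, seed = 2))

estimate_noise_std(noisy)          # additive-equivalent noise scale
#> [1] 0.0607983

report <- evaluate_denoisers(clean, speckle_params(0.2),
                             methods = c("kmeans", "nlm", "nlm-grad", "knl"),
                             seeds = 100:119,
                             config = knl_config(cluster_seed = 1))
report
#> Speckle denoising benchmark (sigma = 0.2, 20 seeds)
#>   noisy     PSNR  21.18 +/-  0.06 dB   MSE 0.00762 +/- 0.00010
#>   kmeans    PSNR  28.17 +/-  0.12 dB   MSE 0.00152 +/- 0.00004
#>   nlm       PSNR  30.52 +/-  0.18 dB   MSE 0.00089 +/- 0.00004
#>   nlm-grad  PSNR  23.72 +/-  0.03 dB   MSE 0.00424 +/- 0.00003
#>   knl       PSNR  30.89 +/-  0.16 dB   MSE 0.00082 +/- 0.00003
```

Each row is the seed-mean quality of one method against the clean
phantom: the speckled input sits near 21 dB; quantizing pixels to
their K-means cluster centers recovers ~28 dB on this
piecewise-constant scene; plain NL-Means reaches ~30.5 dB; and
restricting its candidates to same-class pixels (KNL-Means) adds a
further few tenths of a dB by keeping averaging within tissue classes
(the margin depends on the clustering optimum the seed lands in). The
MSE column carries the same ordering reversed. The gradient variant at
the shared default bandwidth trades peak PSNR for stronger
suppression of detail-region mixing (see the methods vignette).

Doppler resistive index:

```r
resistive_index(100, 37)
#> [1] 0.63
batch_ri(data.frame(group = "B", psv = c(100, 90), edv = c(37, 36)))$summary
#>   group n  mean         sd n_invalid
#> 1     B 2 0.615 0.02121320         0
```

## Command line

An installed thin wrapper (`exec/knlmeans`) drives the same
functions:

```sh
knlmeans simulate --height 128 --width 128 --sigma 0.2 --seed 7 \
         --out clean.png --noisy noisy.png
knlmeans denoise  --method knl --k 4 --in noisy.png --out out.png --ref clean.png
knlmeans evaluate --clean clean.png --sigma 0.2 --seeds 0:19 \
         --methods kmeans,nlm,knl --out report.json
knlmeans ri --in doppler.csv --out ri.csv --summary summary.json
```

Every run is deterministic given `--seed` and writes a manifest JSON
with its fully resolved configuration; `--config file.yaml` preloads
flag values.

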