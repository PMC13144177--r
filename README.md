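# lifhsi

Pixel-wise detection and mapping of fluorescent organic contaminants —
typically sunscreen UV filters such as ethylhexyl methoxycinnamate (EHMC) —
on crystalline food matrices (sea salt) from laser-induced fluorescence
(LIF) hyperspectral image cubes.

Under 450 nm laser excitation, sunscreen residues emit a strong
Stokes-shifted fluorescence band at 480–520 nm while clean salt shows only
a flat 200–400-count background, so each pixel's spectrum carries a
chemical fingerprint of contamination. `lifhsi` turns a raw
rows × cols × bands cube into a contamination map through five stages:

1. **Radiometric calibration** — two-point correction against white/dark
   reference frames: `R_f = (R_o − R_D) / (R_B − R_D)`.
2. **Spectral preprocessing** — laser-band removal (< 480 nm; 17 of 128
   bands on the standard grid), per-spectrum 10th-percentile baseline
   subtraction, negative clipping, trapezoid area normalization, and
   Savitzky–Golay smoothing (order 3, window 11).
3. **Sparse PCA** — the core feature extractor. Loading vectors are found
   by power iteration with an *adaptive relative soft-threshold*,

   ```
   z = Xᵀ(X v),   τ = λ · max|z|,   v ← S(z, τ) / ‖S(z, τ)‖₂
   ```

   where `S(z, τ) = sign(z)·max(|z| − τ, 0)`, followed by Hotelling
   deflation `X ← X − (X v)vᵀ` between components. Scaling the threshold
   to each component's own signal magnitude keeps sparsity consistent
   across components of very different variance, so weak secondary
   emission bands survive alongside the dominant peak. At λ = 0 the
   scheme reduces to ordinary PCA.
4. **RBF-SVM classification** — soft-margin machine (C = 1, kernel scale
   from the median pairwise distance, standardized predictors) on the
   sparse scores; 0 = clean, 1 = contaminated.
5. **Spatial evaluation** — ground-truth erosion (radius 1), balanced
   pixel sampling, confusion counts, accuracy / precision / recall / F1,
   class fractions and color-coded error maps (blue TP, green TN, yellow
   FP, red FN).

A synthetic **phantom generator** renders complete scenes — clean and
contaminated pixel spectra, spatially clustered contamination, white/dark
references and a ground-truth mask — so the whole chain is testable
without instrument data.

## Worked example

```r
library(lifhsi)

cfg <- run_config(phantom = phantom_config(seed = 7), seed = 7)
res <- run_pipeline(cfg, verbose = TRUE)
#> [load] cube 200x200x128, 57.8% of truth contaminated
#> [roi] training spectra: 900 clean + 900 contaminated
#> [fit] sparse extractor, nonzero loadings: 101, 6, 5, 6
#> [cv] mean accuracy 1.0000
#> [evaluate] pixel accuracy 1.0000

print(res$spca)
#> <sparse_pca_model> k = 4, lambda = 0.5
#>   nonzero loadings per component: 101, 6, 5, 6
#>   overall sparsity: 73.4%
print(res$metrics)
#> <metrics_report> accuracy 100.00%, precision 1.0000, recall 1.0000, F1 1.0000
```

The run renders a 200 × 200 phantom scene (57.8% contaminated), calibrates
it, harvests 900 + 900 training spectra from two pure 30 × 30 ROIs, fits
k = 4 sparse components at λ = 0.5, trains the SVM, and classifies all
40,000 pixels. Component 1 stays broad (101 non-zero loadings of 111
bands) while components 2–4 concentrate 5–6 non-zero loadings each inside
the planted emission bands — the sparse loadings *are* the diagnostic
wavelengths. Pixel accuracy is evaluated against the eroded ground truth;
an all-clean scene classified with the same models yields zero
contaminated pixels.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "lifhsi", package = "lifhsi")` with subcommands
`simulate`, `calibrate`, `preprocess`, `run`, `compare`, `evaluate`.

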