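---
title: "Methods: sparse-PCA fluorescence mapping of salt contaminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-PCA fluorescence mapping of salt contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifhsi)
```

## The measurement model

A push-broom hyperspectral camera records, for every pixel of a salt
sample under 450 nm laser excitation, an emission spectrum over 128
contiguous bands spanning 400–1000 nm. Organic UV filters (EHMC and
related cinnamates) fluoresce strongly at 480–520 nm with weaker
secondary structure near 550–600 nm, ~800 nm and 980–1000 nm; clean salt
contributes only a flat few-hundred-count background and a residual of
the excitation line. Classification therefore rests on spectral *shape*,
not absolute intensity.

The package assumes: (i) a uniform, endpoint-inclusive wavelength grid —
for 128 bands over 400–1000 nm the spacing is 600/127 ≈ 4.72 nm, the only
uniform grid on which exactly 17 bands fall below the 480 nm cutoff and
111 remain; (ii) additive sensor noise and a dark-current offset removable
by two-point calibration; (iii) per-pixel independence — all spatial
structure in the output map comes from spatial structure in the spectra,
never from smoothing of the predictions.

## Processing stages and their parameters

**Calibration.** `calibrate()` applies `(R_o − R_D)/(R_B − R_D)`
element-wise. References may be full frames or single spectra broadcast
spatially (a panel measurement averaged spatially is a legitimate
reference; both modes are supported because the acquisition protocol may
use either). Denominators below `1e-6 · max(white)` mark dead bands: the
output is set to 0 there and the count recorded in the cube metadata,
rather than propagating infinities.

**Preprocessing** (`preprocess_pipeline()`), in fixed order:

| step | parameter | default | why |
|---|---|---|---|
| laser-band removal | `cutoff_nm` | 480 nm | excitation line + Rayleigh scatter dominate below; half-open rule (≥ 480 kept) reproduces the 17/111 split |
| baseline subtraction | `baseline_percentile` | 10 | scalar per-spectrum percentile removes additive drift without touching peaks; linear-interpolation definition (position q·(n−1)) so results are exactly reproducible |
| negative clipping | — | — | fluorescence is non-negative; also guarantees a non-negative integrand for the next step |
| area normalization | — | trapezoid rule | divides by the integral over the (possibly non-uniform) grid; removes concentration/roughness/illumination scale, leaves shape |
| Savitzky–Golay | `savgol_order`, `savgol_window` | 3, 11 points | attenuates band-to-band noise while preserving peak position/height; terminal half-windows use the polynomial fit over the first/last full window (no mirror padding), which avoids distorting the peak adjacent to the 480 nm cut |

The order is load-bearing: normalizing before clipping would divide by
integrals contaminated by negative lobes, and subtracting baselines after
normalization would destroy the unit integral. A regression test asserts
that a scrambled order produces different output.

The amplitude decibel transform `to_decibel()` (20·log10, floor −120 dB
for values ≤ 1e-6) is provided for display and export only; the
classification path runs on linear normalized intensities. The dB floor
keeps zero-valued pixels finite in plots.

**Sparse PCA** (`fit_sparse_pca()`). Columns are centered *and* scaled to
unit variance ("standardized"; the stricter of the two plausible
conventions, recorded in the model so projection is exact). For each
component, power iteration with an adaptive relative soft-threshold:
`z = Xᵀ(Xv)`, `τ = λ·max|z|` recomputed every iteration, `v = S(z,τ)`
renormalized. A static threshold calibrated on the dominant 480–520 nm
component would annihilate the weak 980–1000 nm features; the relative
rule keeps per-component sparsity comparable. Choices:

- *Initialization*: leading right singular vector of the current deflated
  matrix — deterministic, no RNG sensitivity.
- *Convergence*: `min(‖v − v_old‖, ‖v + v_old‖) < 1e-6` (sign-agnostic,
  since eigenvectors are sign-ambiguous), cap 500 iterations,
  per-component flags recorded.
- *Sign convention*: largest-magnitude loading entry positive.
- *Fallback*: λ ≥ 1 makes τ ≥ max|z| and `S(z,τ) ≡ 0`; the single
  largest-|z| coefficient is retained with a warning instead of aborting,
  so λ-grid scans remain total.
- *Explained variance*: variance of the score column on the original
  standardized matrix. Sparse components are not orthogonal, so these do
  not sum to the total variance; they are reported per component and
  documented as non-additive.
- *Deflation*: Hotelling, `X ← X − (Xv)vᵀ`; since `‖v‖ = 1`, the deflated
  matrix maps `v` to zero (tested to 1e-9·‖X‖).

`fit_standard_pca()` computes the dense baseline by exact SVD and records
λ = 0; at λ = 0 the sparse fit agrees with it to |cosine| > 1 − 1e-6
(oracle test over random matrices).

**Hyperparameter scans.** `select_k()` (k = 1…12) and `scan_lambda()`
(grid 0.001–2.0) evaluate stratified 5-fold CV accuracy of the full
sparse-PCA + SVM pipeline, *refitting the extractor inside each training
fold* — fitting loadings on all data before splitting would leak held-out
information. The qualitative "performance plateau / maximal sparsity at
no loss" selection is operationalized as a one-standard-error rule:
smallest k (largest λ) whose mean CV accuracy is within one standard
error of the best. Deflation makes components nested, so one fit at
max(k) serves every candidate k per fold.

**Classification.** `train_svm()` standardizes the scores, resolves the
RBF kernel scale σ as the median pairwise Euclidean distance among
standardized training points (the deterministic, full-sample version of
the usual "auto" heuristic; kernel `exp(−‖x−y‖²/(2σ²))`), and trains a
soft-margin machine at C = 1 via libsvm (`e1071`). Predictions are the
hard sign of the decision function; no probability calibration, matching
the hard maps the workflow produces. `classify_cube()` is exactly
row-wise prediction on the flattened cube — spatial order is bookkeeping,
and a test asserts it.

**Evaluation.** The positive class is "contaminated" everywhere.
Ground-truth hygiene before scoring: `erode_mask()` shrinks the class-1
region with a 3 × 3 square structuring element (radius 1,
8-connectivity; border treated as background), converting removed pixels
to unlabeled (255) so mixed boundary pixels never count for or against
the classifier. Metrics follow the four standard formulas; undefined
precision/recall (zero denominator) is flagged `NA` rather than coerced
to 0 or 1, so degenerate CV folds cannot silently bias summaries. Report
formatting rounds accuracy to 2 dp as percent and the others to 4 dp.
Class fractions are computed over labeled pixels by default, with an
`include_unlabeled` mode exposed because either convention is defensible
for whole-map summaries.

## The phantom generator

`render_scene()` emulates: clean-salt spectra (flat level drawn uniformly
from 200–400 counts plus a Gaussian laser residual at 450 nm),
contaminated spectra adding Gaussian emission peaks (main: 500 nm center,
40 nm FWHM, 4100 counts; secondary: 575/750/990 nm at 400/250/220 counts
— roughly 5–10% of the main amplitude), amplitude-linear concentration
scaling, a spatially clustered contamination field (smoothed Gaussian
random field thresholded at the target-fraction quantile, default 57.8%
cover, correlation length 10 px), additive Gaussian sensor noise
(σ = 30 counts), a dark-current offset (100 counts), and a white panel
frame (3000 counts, ≤ 2% smooth nonuniformity). Defaults not fixed by the
emulated acquisition were chosen once as field-plausible values: the
800-count laser residual is "faint" relative to the 4100-count emission
but visible above the background, as in real clean-salt spectra; the
noise level gives a ≳ 100:1 peak SNR typical of a cooled CCD at these
integration times. A `concentration_scale ≈ 0.5` setting emulates the
near-detection-limit regime for stress testing only.

What the phantom does *not* model: scattering physics of the crystal
matrix (TiO₂, surface roughness), photobleaching, wavelength-dependent
white-panel response, stray light, and mixed pixels at contamination
boundaries beyond what spatial thresholding produces. Consequently,
perfect phantom accuracy demonstrates correctness of the chain — not
real-world performance, where heterogeneous scattering drives accuracy
down to the ~96% regime on instrument data. All phantom randomness flows
from one seed; scenes are bit-reproducible.

## Numerical and interface conventions

- Internal addressing is 1-based with inclusive windows (R convention);
  ROI origins follow the imaging-software convention (x = column,
  y = row), convertible via a flag, since acquisition tools report ROIs
  that way.
- ENVI I/O supports little-endian BSQ/BIL/BIP reads and BSQ writes, data
  types 4 (float32), 5 (float64) and 12 (uint16); auto-write picks uint16
  for integer counts and float64 otherwise so round-trips are bit-exact.
  Masks serialize as 8-bit grayscale PNG with the code set {0, 1, 255}.
- Degenerate inputs fail loudly and early: empty band sets after the
  cutoff, zero-integral spectra (named row), single-class training sets,
  zero median pairwise distance, out-of-bounds ROIs, non-finite data.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
200 × 200-pixel phantoms (40,000 spectra × 128 bands) with 900 + 900
training spectra from two 30 × 30 ROIs and tenfold stratified CV;
model-level tests use 60–80 px scenes. These sizes exercise every code
path, including whole-cube mapping, at interactive runtimes.

## Known limitations

- The SVM stores libsvm support vectors; models serialize to JSON as
  configuration plus sparse loadings, not as a full standalone predictor.
- `select_k()`'s plateau rule can select k = 1 on phantoms whose classes
  are separable along the first component alone — correct behavior under
  the parsimony rule, but not a probe of the k = 4 regime unless the
  scene is made harder (higher noise, weaker scale).
- Sparse explained-variance percentages are non-additive (non-orthogonal
  loadings); cumulative-variance diagnostics come from the dense baseline.
- The dense-vs-sparse comparison on default phantoms saturates (both at
  ceiling); the sparse advantage on heterogeneous real scenes is outside
  what the phantom can demonstrate.
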