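---
title: "Methods: chemometric analysis of adipocyte Raman maps"
author: "adipoRaman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric analysis of adipocyte Raman maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Confocal Raman maps of breast-tissue adipocytes carry subtle biochemical
differences between normal adipocytes (NA) and cancer-associated adipocytes
(CAA) — shifts in lipid unsaturation (C=C stretch near 1655 cm⁻¹, =C–H
stretch near 3010 cm⁻¹), triglyceride ester content (C=O near 1745 cm⁻¹) and
acyl-chain packing (CH₂ stretches at 2840/2880 cm⁻¹) — riding under much
larger nuisance variation: fluorescence baselines, multiplicative scatter,
and, most problematically, carotenoid resonance Raman bands (1004, 1155,
1520 cm⁻¹) whose intensity varies strongly from pixel to pixel because
resonance scattering at 532 nm excitation is temperature-sensitive and
carotenoid content differs between patients. `adipoRaman` implements the
full chain that isolates the biology from the nuisance:

1. **Preprocessing** per spectrum: iterative polynomial baseline correction,
   standard normal variate (SNV) normalization, Savitzky–Golay smoothing,
   zero-offset restoration.
2. **EMSC interference correction**: extended multiplicative scatter
   correction whose interference matrix is built from leading PCA loadings
   of the preprocessed data, neutralizing carotenoid variability.
3. **Discriminant-wavenumber ranking**: a 100-tree random forest (Gini
   impurity) with stratified 10-fold cross-validation; the top 15 channels
   by mean impurity decrease are retained.
4. **Embedding evaluation**: UMAP (spectral initialization) repeated over
   seeds 42–51, the most stable projection retained by minimal mean
   Procrustes disparity, and class separability quantified by the silhouette
   score — before and after feature selection.

Because the original patient spectra are not publicly deposited, the package
ships a synthetic-cohort generator with planted ground truth; every stage is
validated against the planted values.

# The data model

Spectra live in a `RamanSpectra` object (a `SummarizedExperiment`): rows are
wavenumber channels, columns are map pixels, `colData` holds sample id,
tissue class (NA/CAA), weight class (NW/OW), ROI id and stage coordinates.
Acquisition covers two windows — fingerprint and high-wavenumber — with the
silent region omitted; analysis uses the closed intervals 900–1800 and
2700–3100 cm⁻¹. A 30 µm × 30 µm region of interest mapped at 1 µm steps,
borders inclusive, gives 31 × 31 = 961 spectra per map.

# Preprocessing

**Baseline.** "Modified polyfit" iteration: fit an order-*n* polynomial (on
the axis affinely mapped to [−1, 1], using an orthogonal basis for
conditioning), clip the working spectrum to `min(spectrum, fit)`, refit
until the baseline changes by < 1e-6 relative (L2) or 100 iterations. The
order is configurable; the default is 5, a common choice for broad tissue
fluorescence under sharp Raman bands. An exact order-*n* polynomial input is
returned as zeros (its own baseline), which the tests assert at 1e-8 of the
signal range.

**SNV.** `(x − mean) / sd` with the sample standard deviation (ddof = 1, the
conventional SNV; ddof = 0 available). A numerically constant spectrum is a
degeneracy error rather than a division blow-up.

**Savitzky–Golay.** Local least squares via `signal::sgolayfilt`, default
window 11 channels, polynomial order 2 (preserves band shape; exact on
quadratics). Edge samples are handled by the projection-matrix edge rows,
i.e. the polynomial fit of the edge window.

**Zero shift.** Subtract the per-spectrum minimum.

The order of operations is baseline → SNV → smoothing → zero shift, applied
independently per spectrum; the chain is deterministic and the dataset-level
function is bit-identical to composing the four steps manually.

# EMSC with PCA interference components

Each spectrum *s* is decomposed by ordinary least squares as

$$ s = a + \sum_{i=1}^{4} c_i \tilde\lambda^i + b\,r + \sum_{j=1}^{k} d_j g_j + e $$

with reference *r* = dataset mean, λ̃ the axis mapped to [−1, 1]
(conditioning; the design's condition number is recorded on the model), and
interference spectra *g_j* = leading mean-centered PCA loadings of the same
preprocessed dataset. The corrected spectrum is
$(s - a - \sum_i c_i\tilde\lambda^i - \sum_j d_j g_j)/b$: the interference
is neutralized, not merely subtracted, because its fitted share is removed
before the multiplicative normalization. Fits with $|b| \le 10^{-6}$
(spectrum unrelated to the reference) are quarantined rather than aborting a
dataset run.

Design choices worth making explicit:

* **Component count.** Default: the smallest *k* whose cumulative explained
  variance reaches 0.96, capped at 10; a fixed *k* (e.g. 5) is a switch.
  PCA loadings are used raw — the reference absorbs the mean.
* **Correction scope.** EMSC runs on the **concatenated** two-window
  spectra, before any region cutting. The high-wavenumber window contains no
  carotenoid bands, so a per-region interference basis there would be built
  from pure lipid variance and would subtract biology; on the concatenated
  spectra the dominant loadings are carotenoid and baseline-like modes.
  (Analyses downstream — ranking, embedding — are per region.)
* **Limits of the subtraction.** Any class signal that lies inside the
  k-dimensional interference span is removed with it. This is a real
  property of PCA-seeded EMSC, not an implementation artifact; it is why the
  interference basis must be small and dominated by nuisance modes. The
  correction also attenuates class-mean band ratios slightly (the component
  of the class difference parallel to the reference is absorbed by *b*);
  with a single-band 8 % effect the recovered ratio is within 2 %.

# Random-forest ranking

100 CART trees, Gini impurity splitting, fixed seed 42. Class imbalance is
addressed by a class-balanced bootstrap per tree (`strata` + equal
`sampsize`, with replacement). Stratified 10-fold cross-validation reports
held-out accuracy (a diagnostic, not a selection gate), after which the
ensemble is refit on all data. Importance is the mean decrease in Gini
impurity, normalized to sum 1 and mapped to wavenumbers; ties break toward
the lower wavenumber; the top 15 are selected. Fingerprint and
high-wavenumber regions are ranked independently, for each cohort stratum
(all, NW-only, OW-only).

# Embedding and silhouette

UMAP with `n_neighbors = 15`, `min_dist = 0.1`, two output dimensions,
spectral initialization. The embedding is computed by `umap-learn` through a
batched helper (one Python process embeds many matrices × seeds; fixing the
random state makes the layout single-threaded and deterministic). The run is
repeated over seeds 42–51; for each candidate the mean symmetric Procrustes
disparity (optimal translation/rotation/reflection/scaling — UMAP
coordinates have no absolute orientation or scale) to its siblings is
computed and the minimizer retained, numerically tied candidates resolving
to the lowest seed.

Separability is the mean silhouette over points,
$(b - a)/\max(a, b)$ with Euclidean distances on the 2-D coordinates and
NA/CAA as the cluster labels (a per-sample label variant is available).
Singleton clusters are an error rather than a silent 0 — a deliberate
deviation from some library conventions, asserted in the tests. The
implementation is vectorized over a distance matrix and is checked against a
brute-force double loop (and `cluster::silhouette`) to 1e-12.

`compareBeforeAfter()` runs embed → stabilize → silhouette on all channels
and on the top-k selection and reports both scores and their difference.

# The synthetic cohort generator

The generator emulates the study design: 5 normal-weight + 5 obese-weight
patients, one NA and one CAA map each, 30 µm × 30 µm grids at 1 µm
(961 spectra per map), analysis axes 900–1800 and 2700–3100 cm⁻¹ at
1 cm⁻¹. Each spectrum is

```
scatter × [ Σ_bands amplitude × multipliers × profile(ν)
            + α × carotenoid profile(ν) + baseline(ν) ] + noise
```

with a 17-band Lorentzian library (the carotenoid triplet plus the main
lipid bands with their standard assignments; widths 10–20 cm⁻¹, typical of
condensed-phase Raman lines), α log-normal (σ = 0.5, plus a patient-level
mean shift for diet) emulating the temperature-sensitive resonance
intensity, a random order-3 polynomial baseline, log-normal multiplicative
scatter (σ = 0.1) and additive Gaussian noise (sd 0.02).

Three calibration decisions matter and were made once, on scientific
grounds:

* **Class effects are subtle.** CAA multiplies the unsaturation, ester and
  packing bands by 4–10 % (1265: ×1.06, 1655: ×1.08, 1745: ×1.06,
  2840: ×0.96, 2880: ×0.94, 3010: ×1.10); OW shifts unsaturation down
  similarly. Differences of this size are invisible in raw mean spectra —
  exactly the regime that motivates a multivariate pipeline. With large
  (tens of per cent) class effects the class difference becomes a dominant
  PCA mode and the EMSC stage removes it, which contradicts the phenomenon
  being emulated.
* **Spectra are not low-rank.** Real tissue spectra contain many overlapping
  bands whose positions and widths vary with composition. The generator
  therefore jitters every band's center (sd 1 cm⁻¹) and width (log-sd 0.05)
  per spectrum, in addition to per-patient (log-sd 0.10) and per-spectrum
  (log-sd 0.05) amplitude effects. Without this, a 10-component
  interference basis spans essentially every band direction and the
  correction removes all structure.
* **Patient structure is real.** Per-patient multipliers and carotenoid
  levels reproduce the per-sample clustering tendency that embeddings of
  the real data show.

What the generator does **not** emulate: Mie scattering shape distortions,
detector artifacts and cosmic rays (removed by hardware accumulation),
band-shape asymmetry, spatial autocorrelation within a map, and any
within-map biology (droplet boundaries, protein inclusions). Passing tests
therefore demonstrate correctness of the chain under the planted model, not
clinical performance on real tissue.

# Problem sizes used in tests and in the acceptance script

Full-size cohorts (19 220 spectra × 1302 channels) are generated in seconds
but make iterated end-to-end experiments slow, so the validation experiments
run on reduced cohorts chosen to preserve the structure: 3 + 3 patients
(2 + 2 for focused EMSC experiments), 5 µm × 5 µm maps (16 pixels), axes at
4 cm⁻¹ — 300 spectra × 327 channels per cohort, 10 cohort seeds per
experiment. The silhouette-improvement experiment keeps the full UMAP seed
set 42–51. The spectrum count test uses the full 20-map design on a coarse
(8 cm⁻¹) axis, which does not affect counts.

Observed behaviour at this scale mirrors the full design qualitatively:
before feature selection the NA/CAA silhouette on the embedding is ≈ 0
(patient clusters dominate), after top-15 selection it rises to ≈ 0.03–0.21,
and the improvement holds in ≥ 8 of 10 seeds per region. The planted
carotenoid amplitude correlates ≥ 0.93 with the 1155 cm⁻¹ channel before
correction and ≤ ~0.05 in magnitude after.

# Numerical choices and degenerate inputs

* Baseline/EMSC polynomials are formed on the axis mapped to [−1, 1]; the
  baseline uses an orthonormal basis, EMSC uses raw powers but records the
  design condition number and refuses rank-deficient designs, naming the
  collinear column.
* EMSC least squares is solved by QR; coefficients agree with an explicit
  normal-equations solve to 1e-9 on ≤ 50-channel instances (tested on 100
  random instances).
* `b_min = 1e-6` guards the division by the reference coefficient.
* Degenerate inputs fail loudly with context: zero-variance spectra at SNV
  (with the spectrum id), empty region cuts, extrapolating resampling,
  non-monotone axes (descending files are reversed with a notice),
  singleton silhouette clusters, single-class or under-stratified labels.
* Determinism: the full chain is deterministic given the configuration
  seeds; fixed-seed reruns produce bit-identical cohorts, rankings and
  embeddings (UMAP rerun difference is exactly 0 on the same host).

# Known limitations

* The silhouette magnitudes of the original patient data are not
  reproducible without that data; only the direction and rough scale of the
  selection effect are validated, on synthetic cohorts.
* PCA-seeded EMSC cannot distinguish nuisance from biology that shares its
  subspace; the variance threshold / component cap is the only control.
* The embedding step shells out to Python's `umap-learn`; without a Python
  interpreter with `umap-learn` on the PATH the embedding module (and the
  pipeline stages that use it) is unavailable. Determinism across different
  machines/BLAS builds is not guaranteed by upstream, only within a host.
* Cross-validation folds respect class strata but not patient identity;
  with very few patients, fold accuracy can be optimistic relative to a
  leave-patient-out scheme (which the original design does not specify).
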