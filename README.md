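# adipoRaman

Chemometric analysis of confocal Raman hyperspectral maps of breast-tissue
adipocytes: separating cancer-associated adipocytes (CAA) from normal
adipocytes (NA), and profiling obesity-related lipid differences, in the
presence of strong carotenoid resonance Raman interference.

## Who this is for

Raman spectroscopists and computational biologists who map adipose tissue
(or comparable lipid-rich samples) and need a tested, reproducible pipeline
from raw per-pixel spectra to discriminant wavenumbers and separability
scores — including the case where no public patient data exist, via a
synthetic cohort generator with planted ground truth.

## The method

For each spectrum *s* on wavenumber axis ν:

1. **Preprocessing** — iterative polynomial baseline correction (order *n*,
   min-clipping "modified polyfit"), standard normal variate normalization
   `(s − mean)/sd`, Savitzky–Golay smoothing (window 11, order 2), zero
   shift.
2. **EMSC interference correction** — ordinary least squares of

   s = a + Σᵢ cᵢ λ̃ⁱ + b·r + Σⱼ dⱼ gⱼ + e,   i = 1…4

   with reference `r` = dataset mean, λ̃ the axis mapped to [−1, 1], and
   interference spectra `gⱼ` = leading PCA loadings of the preprocessed
   data (smallest k with cumulative explained variance ≥ 0.96, capped at
   10). The corrected spectrum is `(s − a − Σ cᵢλ̃ⁱ − Σ dⱼgⱼ)/b`, which
   neutralizes the temperature-sensitive carotenoid resonance bands (1004,
   1155, 1520 cm⁻¹). Correction runs on the concatenated two-window
   spectra; analysis then splits into the fingerprint (900–1800 cm⁻¹) and
   high-wavenumber (2700–3100 cm⁻¹) regions.
3. **Discriminant wavenumbers** — 100-tree random forest (Gini impurity,
   seed 42, class-balanced bootstrap, stratified 10-fold CV); channels
   ranked by normalized mean impurity decrease; top 15 selected.
4. **Embedding evaluation** — UMAP (spectral init, n_neighbors 15,
   min_dist 0.1) repeated over seeds 42–51, the most stable projection
   retained by minimal mean Procrustes disparity, NA/CAA separability
   scored by the mean silhouette — before vs after feature selection.

## Worked example

```r
library(adipoRaman)

# a reduced synthetic cohort: 3 NW + 3 OW patients, NA + CAA maps,
# 5 x 5 um grids, axes at 4 cm^-1
cfg <- generatorConfig(axisStep = 4, nPatientsPerWeightClass = 3,
                       grid = c(4, 4, 1), seed = 7)
cohort <- generateCohort(cfg)
cohort$spectra
#> RamanSpectra with 327 channels x 300 spectra
#>   wavenumber axis: 900.0 .. 3100.0 cm-1
#>   tissue classes: CAA=150 NA=150
#>   samples: 12

# preprocess each acquisition window, concatenate, EMSC-correct
cc <- correctCohort(cohort$spectra)
cc$basis
#> InterferenceBasis: 10 components x 327 channels
#>   explained variance: 0.684 0.066 0.043 0.032 0.020 0.016 0.014 0.013 0.010 0.009 (cumulative 0.907)

# rank discriminant wavenumbers in the fingerprint region
fp <- cutRegion(cc$corrected, "fingerprint")
fit <- trainRFCV(fp, "tissue_class", rfConfig())
ranking <- rankWavenumbers(fit)
ranking
#> FeatureRanking over 226 wavenumbers
#>   top: 1660 cm-1 (0.015), 1304 cm-1 (0.015), 1508 cm-1 (0.014), 1528 cm-1 (0.014), 1656 cm-1 (0.012)
#>   CV accuracy: 0.627 +/- 0.116

# embedding separability before vs after top-15 selection
cmp <- compareBeforeAfter(fp, ranking, k = 15)
cmp
#> silhouette before selection: 0.005 (seed 47)
#> silhouette after top-15 selection: 0.037 (seed 43)
#> delta: +0.032
```

Reading the output: the interference basis is dominated by one large
carotenoid/baseline mode (68 % of variance). The forest separates NA from
CAA well above chance (CV accuracy 0.63 against a planted ~8 % band
effect), and its top wavenumbers sit on and around the planted unsaturation
band at 1655 cm⁻¹. On all 226 channels the UMAP embedding shows essentially
no NA/CAA separation (silhouette 0.005 — pixels cluster by patient, not by
class); restricting to the 15 discriminant channels raises the silhouette
to 0.037.

The full pipeline (all six partitions × both regions, with artifacts,
manifest and report) is one call:

```r
res <- runPipeline(pipelineConfig(input = list(synth = cfg)), "out/")
writeReport("out/")
```

or from a shell via the thin CLI at `inst/scripts/adipo-raman.R`
(`generate`, `run`, `report` subcommands, YAML config).

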