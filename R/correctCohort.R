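#' Preprocess acquisition windows and EMSC-correct the concatenated spectra
#'
#' The standard correction chain for a two-window acquisition: each window is
#' preprocessed independently (baseline, SNV, Savitzky--Golay, zero shift --
#' the windows are acquired separately and carry independent baselines), the
#' windows are concatenated, and extended multiplicative scatter correction
#' with PCA-derived interference components is applied to the concatenated
#' spectra. Correction precedes any region cutting for analysis: the
#' carotenoid interference lives in the fingerprint window, but the
#' multiplicative normalization and interference neutralization must act on
#' the whole spectrum.
#'
#' @param x a [RamanSpectra-class] covering all acquisition windows.
#' @param windows list of [SpectralRegion-class]s or region names (default
#'   the fingerprint and high-wavenumber analysis windows).
#' @param preConfig a [preprocessConfig()].
#' @param polyOrder EMSC polynomial order (default 4).
#' @param nComponents fixed interference component count, or `NULL` to
#'   select by `varianceThreshold`.
#' @param varianceThreshold cumulative explained-variance target
#'   (default 0.96, capped at `maxComponents`).
#' @param maxComponents cap on the selected component count (default 10).
#' @param bMin EMSC degenerate-fit guard.
#' @return list with `corrected` (concatenated, corrected `RamanSpectra`),
#'   `preprocessed`, `basis`, `model`, `coefficients`, `quarantine`.
#' @export
correctCohort <- function(x,
                          windows = list("fingerprint", "high_wavenumber"),
                          preConfig = preprocessConfig(),
                          polyOrder = 4L, nComponents = NULL,
                          varianceThreshold = 0.96, maxComponents = 10L,
                          bMin = 1e-6) {
  pres <- lapply(windows, function(w) {
    if (is.character(w)) w <- spectralRegion(w)
    preprocessSpectra(cutRegion(x, w), preConfig)
  })
  wn <- unlist(lapply(pres, wavenumbers))
  Y <- do.call(rbind, lapply(pres, intensityMatrix))
  pre <- RamanSpectra(wn, Y, spectrumMeta(pres[[1]]))
  basis <- extractInterferenceComponents(
    pre, nComponents = nComponents,
    varianceThreshold = varianceThreshold, maxComponents = maxComponents)
  model <- buildEMSCModel(pre, polyOrder = polyOrder, interference = basis,
                          bMin = bMin)
  corr <- correctSpectra(pre, model)
  list(corrected = corr$spectra, preprocessed = pre, basis = basis,
       model = model, coefficients = corr$coefficients,
       quarantine = corr$quarantine)
}
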