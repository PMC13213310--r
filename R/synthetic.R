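#' Default Raman band library for adipocyte spectra
#'
#' Lorentzian band positions and assignments of the main lipid and carotenoid
#' features of adipose tissue: the carotenoid triplet near 1004 / 1155 /
#' 1520 cm\eqn{^{-1}} (resonance-enhanced at 532 nm excitation, hence the
#' strongly variable amplitude that the EMSC stage neutralizes), the
#' fingerprint lipid bands (CH\eqn{_2} scissoring 1440, C=C stretch 1655,
#' ester C=O 1745) and the C--H stretching bands of the high-wavenumber
#' region (symmetric CH\eqn{_2} 2840, asymmetric CH\eqn{_2} 2880, =C--H 3010).
#' Band widths default to 10--20 cm\eqn{^{-1}}, typical of condensed-phase
#' Raman lines.
#'
#' @return `data.frame` with columns `label`, `center`, `fwhm`, `amplitude`,
#'   `shape`, `carotenoid`, `assignment`.
#' @export
adipoBandLibrary <- function() {
  data.frame(
    label = c("b971", "b1004", "b1065", "b1080", "b1119", "b1155",
              "b1265", "b1301", "b1440", "b1520", "b1655", "b1745",
              "b2840", "b2880", "b2935", "b2970", "b3010"),
    center = c(971, 1004, 1065, 1080, 1119, 1155,
               1265, 1301, 1440, 1520, 1655, 1745,
               2840, 2880, 2935, 2970, 3010),
    fwhm = c(10, 10, 14, 16, 14, 14,
             18, 18, 18, 16, 16, 14,
             20, 20, 20, 20, 18),
    amplitude = c(0.15, 0.2, 0.5, 0.4, 0.35, 0.6,
                  0.45, 0.9, 1.0, 1.0, 0.7, 0.4,
                  2.0, 1.6, 1.2, 0.6, 0.5),
    shape = "lorentzian",
    carotenoid = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                   FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE),
    assignment = c(
      "=C-H out-of-plane deformation",
      "C-C stretch + CH3 rock (carotenoid/phenylalanine)",
      "C-C skeletal stretch (trans chain)",
      "C-C skeletal stretch (gauche chain)",
      "C-C skeletal stretch (lipids)",
      "C-C stretch (carotenoid)",
      "=C-H in-plane deformation (unsaturated lipids)",
      "CH2 twisting (lipids)",
      "CH2 scissoring (lipids)",
      "C=C stretch (carotenoid, resonance-enhanced)",
      "C=C stretch (unsaturated lipids) / amide I",
      "C=O ester stretch (triglycerides)",
      "symmetric CH2 stretch (lipid acyl chains)",
      "asymmetric CH2 stretch (lipid acyl chains)",
      "CH3 symmetric stretch",
      "CH3 asymmetric stretch",
      "=C-H stretch (cis double bonds)"),
    stringsAsFactors = FALSE)
}

#' Class-effect profiles for the synthetic cohort
#'
#' Multiplicative band effects of the tissue classes (normal adipocyte `NA`
#' is the identity reference; cancer-associated `CAA` carries higher
#' unsaturation-related intensity at 1655 and 3010 cm\eqn{^{-1}}, a higher
#' ester band and looser chain packing) and of the weight classes (`NW`
#' identity; `OW` shifted toward lower unsaturation and denser packing).
#' The effects are deliberately subtle (5--10%): the biochemical differences
#' between adipocyte classes are below what is visible in raw mean spectra
#' and smaller than the carotenoid resonance variability, which is exactly
#' the regime the multivariate pipeline is built for.
#'
#' @return named list of named multiplier vectors (band labels).
#' @export
defaultClassProfiles <- function() {
  list(
    "NA" = c(),
    "CAA" = c(b1265 = 1.06, b1655 = 1.08, b1745 = 1.06,
              b2840 = 0.96, b2880 = 0.94, b3010 = 1.10),
    "NW" = c(),
    "OW" = c(b1655 = 0.95, b3010 = 0.93, b2880 = 1.05))
}

#' Synthetic-cohort generator configuration
#'
#' The defaults emulate the acquisition design of a two-window confocal Raman
#' mapping study of breast adipocytes: analysis axes 900--1800 and
#' 2700--3100 cm\eqn{^{-1}} at 1 cm\eqn{^{-1}}, 5 normal-weight + 5
#' obese-weight patients, one normal (`NA`) and one cancer-associated
#' (`CAA`) tissue map per patient, each a 30 um x 30 um region at 1 um step
#' (961 spectra). Spectrum-to-spectrum carotenoid resonance variability is
#' lognormal; baseline drift is a random polynomial; global multiplicative
#' scatter is lognormal; noise is additive Gaussian.
#'
#' @param regions named list of axis ranges (cm\eqn{^{-1}}).
#' @param axisStep channel spacing (cm\eqn{^{-1}}, default 1).
#' @param nPatientsPerWeightClass patients per `NW`/`OW` stratum (default 5).
#' @param grid `c(width_um, height_um, step_um)` of each map (default
#'   30, 30, 1).
#' @param bands band library `data.frame` (see [adipoBandLibrary()]).
#' @param classProfiles named list of multiplier vectors (see
#'   [defaultClassProfiles()]).
#' @param carotenoidMeanlog,carotenoidSdlog lognormal parameters of the
#'   per-spectrum carotenoid amplitude (defaults 0, 0.5).
#' @param carotenoidDist `"lognormal"` (default; strictly positive and
#'   heavy-tailed, emulating the temperature sensitivity of resonance Raman
#'   intensities) or `"uniform"` on `carotenoidRange`.
#' @param carotenoidRange amplitude range used when
#'   `carotenoidDist = "uniform"` (default `c(0.5, 2)`).
#' @param patientCarotenoidSdlog between-patient sd of the carotenoid
#'   meanlog (diet differences; default 0.3).
#' @param patientEffectSdlog between-patient lognormal sd of every band
#'   multiplier (default 0.10).
#' @param spectrumJitterSdlog within-map per-spectrum lognormal band
#'   amplitude jitter (default 0.05).
#' @param bandCenterJitterSd per-spectrum Gaussian jitter of each band
#'   center in cm\eqn{^{-1}} (default 1; composition-driven band shifts make
#'   real spectra full-rank rather than a fixed low-rank band mixture).
#' @param bandWidthJitterSdlog per-spectrum lognormal jitter of each band
#'   width (default 0.05).
#' @param baselineOrder,baselineScale order and coefficient scale of the
#'   random polynomial baseline (defaults 3, 0.3).
#' @param scatterSdlog lognormal sd of the global multiplicative scatter
#'   factor (default 0.1).
#' @param noiseSd additive Gaussian noise sd (default 0.02).
#' @param seed cohort seed; a fixed seed reproduces the cohort bit-exactly.
#' @return a list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(regions = list(fingerprint = c(900, 1800),
                                           high_wavenumber = c(2700, 3100)),
                            axisStep = 1, nPatientsPerWeightClass = 5L,
                            grid = c(30, 30, 1),
                            bands = adipoBandLibrary(),
                            classProfiles = defaultClassProfiles(),
                            carotenoidMeanlog = 0, carotenoidSdlog = 0.5,
                            carotenoidDist = c("lognormal", "uniform"),
                            carotenoidRange = c(0.5, 2),
                            patientCarotenoidSdlog = 0.3,
                            patientEffectSdlog = 0.10,
                            spectrumJitterSdlog = 0.05,
                            bandCenterJitterSd = 1,
                            bandWidthJitterSdlog = 0.05,
                            baselineOrder = 3L, baselineScale = 0.3,
                            scatterSdlog = 0.1, noiseSd = 0.02,
                            seed = 1L) {
  stopifnot(axisStep > 0, nPatientsPerWeightClass >= 1,
            carotenoidSdlog >= 0, patientEffectSdlog >= 0,
            spectrumJitterSdlog >= 0, bandCenterJitterSd >= 0,
            bandWidthJitterSdlog >= 0, baselineScale >= 0,
            scatterSdlog >= 0, noiseSd >= 0)
  carotenoidDist <- match.arg(carotenoidDist)
  structure(as.list(environment()), class = "GeneratorConfig")
}

.generatorAxis <- function(config) {
  unlist(lapply(config$regions, function(r)
    seq(r[1], r[2], by = config$axisStep)), use.names = FALSE)
}

.bandProfiles <- function(axis, bands) {
  # channels x bands matrix of unit-height band shapes
  P <- vapply(seq_len(nrow(bands)), function(i) {
    c0 <- bands$center[i]; w <- bands$fwhm[i]
    if (bands$shape[i] == "gaussian")
      exp(-4 * log(2) * (axis - c0)^2 / w^2)
    else
      (w / 2)^2 / ((axis - c0)^2 + (w / 2)^2)
  }, numeric(length(axis)))
  colnames(P) <- bands$label
  P
}

.profileMultipliers <- function(bands, profile) {
  m <- rep(1, nrow(bands))
  names(m) <- bands$label
  if (length(profile)) {
    known <- intersect(names(profile), bands$label)
    m[known] <- m[known] * profile[known]
  }
  m
}

#' Generate one synthetic spectrum
#'
#' Deterministic band synthesis (noise excepted):
#' `intensity = scatter * (band profiles %*% (amplitude * multipliers)
#'  + carotenoidAmp * carotenoid profile + baseline polynomial) + noise`.
#' Carotenoid-flagged bands are scaled by `carotenoidAmp`; the remaining
#' bands by their multipliers.
#'
#' @param axis wavenumber axis.
#' @param bands band library `data.frame`.
#' @param multipliers named multiplier vector over band labels (default all
#'   1).
#' @param carotenoidAmp carotenoid resonance amplitude (default 1).
#' @param baselineCoefs polynomial baseline coefficients on the axis mapped
#'   to \eqn{[-1, 1]} (constant first; default none).
#' @param scatter global multiplicative factor (default 1).
#' @param noiseSd additive Gaussian noise sd (default 0; drawn from the
#'   caller's RNG stream).
#' @return numeric intensity vector.
#' @export
generateSpectrum <- function(axis, bands = adipoBandLibrary(),
                             multipliers = NULL, carotenoidAmp = 1,
                             baselineCoefs = numeric(), scatter = 1,
                             noiseSd = 0) {
  P <- .bandProfiles(axis, bands)
  m <- rep(1, nrow(bands)); names(m) <- bands$label
  if (!is.null(multipliers)) {
    known <- intersect(names(multipliers), bands$label)
    m[known] <- multipliers[known]
  }
  amp <- bands$amplitude * m
  amp[bands$carotenoid] <- bands$amplitude[bands$carotenoid] *
    m[bands$carotenoid] * carotenoidAmp
  y <- as.numeric(P %*% amp)
  if (length(baselineCoefs)) {
    lam <- .scaleAxis(axis)
    y <- y + as.numeric(outer(lam, seq_along(baselineCoefs) - 1, `^`) %*%
                          baselineCoefs)
  }
  y <- scatter * y
  if (noiseSd > 0) y <- y + stats::rnorm(length(axis), 0, noiseSd)
  y
}

#' Generate a synthetic adipocyte cohort
#'
#' Draws a full cohort under the configured study design: per patient, one
#' `NA` and one `CAA` map on the configured grid; band multipliers combine
#' tissue-class and weight-class profiles with patient-level lognormal
#' effects and per-spectrum jitter; each spectrum receives a lognormal
#' carotenoid amplitude, a random polynomial baseline, a lognormal scatter
#' factor and additive noise. All planted parameters are returned in a
#' ground-truth table so downstream oracles can verify recovery.
#'
#' @param config a [generatorConfig()].
#' @return list with `spectra` (a [RamanSpectra-class]) and `truth`
#'   (`data.frame`: one row per spectrum with the planted carotenoid
#'   amplitude, scatter, baseline coefficients and effective band
#'   multipliers).
#' @export
generateCohort <- function(config = generatorConfig()) {
  set.seed(config$seed)
  axis <- .generatorAxis(config)
  bands <- config$bands
  P <- .bandProfiles(axis, bands)
  lam <- .scaleAxis(axis)
  BL <- outer(lam, 0:config$baselineOrder, `^`)
  grid <- buildMapGrid(config$grid[1], config$grid[2], config$grid[3])
  npix <- nrow(grid)
  nb <- nrow(bands)

  sample_ids <- character(); meta <- list(); truth <- list()
  cols <- list()
  si <- 0L
  for (wc in c("NW", "OW")) {
    for (pidx in seq_len(config$nPatientsPerWeightClass)) {
      patientMult <- exp(stats::rnorm(nb, 0, config$patientEffectSdlog))
      names(patientMult) <- bands$label
      patientCarotMeanlog <- config$carotenoidMeanlog +
        stats::rnorm(1, 0, config$patientCarotenoidSdlog)
      for (tc in c("NA", "CAA")) {
        sid <- paste0(wc, pidx, "_", tc)
        classMult <- .profileMultipliers(bands, config$classProfiles[[tc]]) *
          .profileMultipliers(bands, config$classProfiles[[wc]])
        jitter <- matrix(exp(stats::rnorm(nb * npix, 0,
                                          config$spectrumJitterSdlog)),
                         nb, npix)
        mult <- (bands$amplitude * classMult * patientMult) * jitter
        carot <- if (config$carotenoidDist == "uniform")
          stats::runif(npix, config$carotenoidRange[1],
                       config$carotenoidRange[2])
        else
          stats::rlnorm(npix, patientCarotMeanlog, config$carotenoidSdlog)
        mult[bands$carotenoid, ] <-
          sweep(mult[bands$carotenoid, , drop = FALSE], 2, carot, `*`)
        blCoef <- matrix(stats::rnorm((config$baselineOrder + 1) * npix,
                                      0, config$baselineScale),
                         config$baselineOrder + 1, npix)
        blCoef[1, ] <- abs(blCoef[1, ]) + 2 * config$baselineScale
        scatter <- stats::rlnorm(npix, 0, config$scatterSdlog)
        centerJit <- matrix(stats::rnorm(nb * npix, 0,
                                         config$bandCenterJitterSd),
                            nb, npix)
        widthJit <- matrix(exp(stats::rnorm(nb * npix, 0,
                                            config$bandWidthJitterSdlog)),
                           nb, npix)
        if (config$bandCenterJitterSd == 0 &&
            config$bandWidthJitterSdlog == 0) {
          Y <- P %*% mult
        } else {
          Y <- matrix(0, length(axis), npix)
          bpx <- bands
          for (px in seq_len(npix)) {
            bpx$center <- bands$center + centerJit[, px]
            bpx$fwhm <- bands$fwhm * widthJit[, px]
            Y[, px] <- .bandProfiles(axis, bpx) %*% mult[, px]
          }
        }
        Y <- sweep(Y + BL %*% blCoef, 2, scatter, `*`)
        if (config$noiseSd > 0)
          Y <- Y + matrix(stats::rnorm(length(Y), 0, config$noiseSd),
                          nrow(Y), ncol(Y))
        ids <- paste0(sid, "_px", seq_len(npix))
        colnames(Y) <- ids
        si <- si + 1L
        cols[[si]] <- Y
        meta[[si]] <- data.frame(
          spectrum_id = ids, sample_id = sid, tissue_class = tc,
          weight_class = wc, roi_id = paste0(sid, "_roi1"),
          x_um = grid$x_um, y_um = grid$y_um,
          stringsAsFactors = FALSE)
        tr <- data.frame(spectrum_id = ids, sample_id = sid,
                         tissue_class = tc, weight_class = wc,
                         carotenoid_amp = carot, scatter = scatter,
                         stringsAsFactors = FALSE)
        for (bi in seq_len(config$baselineOrder + 1))
          tr[[paste0("baseline_c", bi - 1)]] <- blCoef[bi, ]
        effMult <- classMult * patientMult
        for (b in bands$label)
          tr[[paste0("mult_", b)]] <- effMult[[b]] * jitter[match(b, bands$label), ]
        truth[[si]] <- tr
      }
    }
  }
  Y <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(spectra = RamanSpectra(axis, Y, meta), truth = truth)
}
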