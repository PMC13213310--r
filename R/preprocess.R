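#' Preprocessing configuration
#'
#' Parameters of the four-step per-spectrum preprocessing chain: iterative
#' polynomial baseline correction, standard normal variate (SNV)
#' normalization, Savitzky--Golay smoothing, and zero-offset restoration.
#'
#' @param baselineOrder polynomial order of the baseline (>= 0; default 5 --
#'   suits broad fluorescence under sharp Raman bands).
#' @param baselineMaxIter maximum min-clipping iterations (default 100).
#' @param baselineTol relative convergence tolerance on the fitted baseline
#'   (default 1e-6).
#' @param savgolWindow odd smoothing window in channels (>= 5, default 11).
#' @param savgolPolyorder local polynomial order of the smoother (default 2).
#' @param snvDdof 0 (population) or 1 (sample, the conventional SNV) degrees
#'   of freedom for the standard deviation.
#' @return a validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(baselineOrder = 5L, baselineMaxIter = 100L,
                             baselineTol = 1e-6, savgolWindow = 11L,
                             savgolPolyorder = 2L, snvDdof = 1L) {
  if (baselineOrder < 0) stop("baselineOrder must be >= 0")
  if (baselineMaxIter < 1) stop("baselineMaxIter must be >= 1")
  if (savgolWindow %% 2 != 1 || savgolWindow < 5)
    stop("savgolWindow must be an odd integer >= 5")
  if (savgolPolyorder >= savgolWindow)
    stop("savgolPolyorder must be < savgolWindow")
  if (!snvDdof %in% c(0L, 1L)) stop("snvDdof must be 0 or 1")
  structure(list(baselineOrder = as.integer(baselineOrder),
                 baselineMaxIter = as.integer(baselineMaxIter),
                 baselineTol = baselineTol,
                 savgolWindow = as.integer(savgolWindow),
                 savgolPolyorder = as.integer(savgolPolyorder),
                 snvDdof = as.integer(snvDdof)),
            class = "PreprocessConfig")
}

# Orthonormal polynomial basis (including intercept) on the axis mapped to
# [-1, 1]; columns have unit norm, so projection is Q %*% crossprod(Q, y).
.polyBasis <- function(wavenumber, order) {
  n <- length(wavenumber)
  if (order >= n)
    stop("fit error: polynomial order ", order,
         " too high for ", n, " channels")
  lam <- .scaleAxis(wavenumber)
  if (order == 0) {
    Q <- matrix(1 / sqrt(n), n, 1)
  } else {
    Q <- cbind(1 / sqrt(n), stats::poly(lam, degree = order, raw = FALSE))
  }
  unname(Q)
}

.scaleAxis <- function(wavenumber) {
  rng <- range(wavenumber)
  if (diff(rng) == 0) stop("degenerate wavenumber axis")
  2 * (wavenumber - rng[1]) / diff(rng) - 1
}

#' Iterative polynomial baseline correction
#'
#' Fits an order-`n` polynomial to the spectrum, clips the working spectrum
#' to the pointwise minimum of itself and the fit, and refits until the
#' baseline changes by less than `baselineTol` (relative L2) or
#' `baselineMaxIter` iterations -- the modified-polyfit scheme that lets
#' broad fluorescence pass underneath sharp Raman bands.
#'
#' @param y numeric spectrum.
#' @param wavenumber matching wavenumber axis (polynomials are formed on the
#'   axis mapped to \eqn{[-1, 1]}).
#' @param config a [preprocessConfig()] (fields `baselineOrder`,
#'   `baselineMaxIter`, `baselineTol` are used).
#' @return list with `corrected` (`y - baseline`) and `baseline`.
#' @export
baselineCorrect <- function(y, wavenumber, config = preprocessConfig()) {
  if (!all(is.finite(y))) stop("spectrum must be finite")
  Q <- .polyBasis(wavenumber, config$baselineOrder)
  w <- y
  fit_prev <- NULL
  for (it in seq_len(config$baselineMaxIter)) {
    fit <- as.numeric(Q %*% crossprod(Q, w))
    if (!all(is.finite(fit))) stop("fit error: baseline fit diverged")
    if (!is.null(fit_prev)) {
      denom <- max(sqrt(sum(fit^2)), .Machine$double.eps)
      if (sqrt(sum((fit - fit_prev)^2)) / denom < config$baselineTol) break
    }
    fit_prev <- fit
    w <- pmin(w, fit)
  }
  list(corrected = y - fit, baseline = fit)
}

#' Standard normal variate normalization
#'
#' Centers a spectrum to mean 0 and scales it to unit standard deviation.
#'
#' @param y numeric spectrum.
#' @param ddof degrees of freedom of the standard deviation (1 = sample sd,
#'   the conventional SNV; 0 = population sd).
#' @return the normalized spectrum.
#' @export
snvNormalize <- function(y, ddof = 1) {
  m <- mean(y)
  n <- length(y)
  s <- sqrt(sum((y - m)^2) / (n - ddof))
  # relative guard: a numerically constant spectrum has sd at rounding level
  if (!is.finite(s) || s <= 1e-13 * (abs(m) + 1))
    stop("degenerate spectrum: zero variance, SNV undefined")
  (y - m) / s
}

#' Savitzky--Golay smoothing
#'
#' Local least-squares polynomial smoothing; edges are handled by fitting the
#' polynomial of the edge window (the projection-matrix transient rows), so
#' polynomials of degree <= `polyorder` pass through unchanged.
#'
#' @param y numeric spectrum.
#' @param window odd window length in channels.
#' @param polyorder local polynomial order (default 2).
#' @return the smoothed spectrum.
#' @export
savgolSmooth <- function(y, window = 11, polyorder = 2) {
  if (window %% 2 != 1) stop("parameter error: window must be odd")
  if (polyorder >= window) stop("parameter error: polyorder must be < window")
  if (window > length(y)) stop("parameter error: window exceeds spectrum length")
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window))
}

#' Shift a spectrum back to zero intensity
#'
#' Subtracts the per-spectrum minimum so the corrected baseline sits at zero.
#'
#' @param y numeric spectrum.
#' @return spectrum with minimum exactly 0.
#' @export
zeroOffset <- function(y) {
  if (!all(is.finite(y))) stop("spectrum must be finite")
  y - min(y)
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, independently per spectrum and in this order: (1) iterative
#' polynomial baseline correction, (2) SNV normalization, (3)
#' Savitzky--Golay smoothing, (4) zero-offset restoration.
#'
#' @param x a [RamanSpectra-class] object.
#' @param config a [preprocessConfig()].
#' @param verbose emit per-step summaries via `message()`.
#' @return the preprocessed `RamanSpectra` (same axis and metadata).
#' @export
preprocessSpectra <- function(x, config = preprocessConfig(), verbose = FALSE) {
  wn <- wavenumbers(x)
  Y <- intensityMatrix(x)
  ids <- colnames(Y)
  .polyBasis(wn, config$baselineOrder)  # fail fast if order too high
  out <- Y
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    step <- "baseline"
    res <- tryCatch({
      bl <- baselineCorrect(y, wn, config)
      step <- "snv"
      y2 <- snvNormalize(bl$corrected, config$snvDdof)
      step <- "savgol"
      y3 <- savgolSmooth(y2, config$savgolWindow, config$savgolPolyorder)
      step <- "zero_offset"
      zeroOffset(y3)
    }, error = function(e)
      stop("preprocessing failed at step '", step, "' for spectrum '",
           ids[j], "': ", conditionMessage(e), call. = FALSE))
    out[, j] <- res
  }
  if (verbose)
    message("preprocessed ", ncol(Y), " spectra (baseline order ",
            config$baselineOrder, ", SG window ", config$savgolWindow,
            "/order ", config$savgolPolyorder, ", SNV ddof ",
            config$snvDdof, ")")
  SummarizedExperiment::assay(x, "intensity") <- out
  x
}
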