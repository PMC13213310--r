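#' Extract PCA interference components from a spectral dataset
#'
#' Mean-centered principal component analysis of the (pre-processed) spectra;
#' the leading loadings capture the dominant correlated variations -- in
#' adipocyte maps these are chiefly the carotenoid resonance bands, whose
#' intensity varies spectrum-to-spectrum with local temperature -- and are
#' used as interference spectra in the EMSC design.
#'
#' Either a fixed number of components is returned, or the smallest number
#' whose cumulative explained variance reaches `varianceThreshold`
#' (default 0.96, capped at `maxComponents`).
#'
#' @param x a [RamanSpectra-class] object (>= 2 spectra).
#' @param nComponents fixed component count (overrides the threshold rule).
#' @param varianceThreshold cumulative explained-variance target in (0, 1].
#' @param maxComponents cap on the threshold-selected count (default 10).
#' @return an [InterferenceBasis-class].
#' @export
extractInterferenceComponents <- function(x, nComponents = NULL,
                                          varianceThreshold = 0.96,
                                          maxComponents = 10L) {
  Y <- t(intensityMatrix(x))          # spectra x channels
  if (nrow(Y) < 2) stop("need at least 2 spectra for PCA")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  rank <- sum(v > max(v) * 1e-12)
  evr <- v / sum(v)
  if (!is.null(nComponents)) {
    k <- as.integer(nComponents)
    if (k > rank)
      stop("rank error: requested ", k, " components but data rank is ", rank)
  } else {
    k <- which(cumsum(evr) >= varianceThreshold - 1e-12)[1]
    if (is.na(k)) k <- rank
    k <- min(k, maxComponents, rank)
  }
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])
  dimnames(comp) <- NULL
  new("InterferenceBasis", components = comp,
      explainedVarianceRatio = evr[seq_len(k)])
}

setMethod("show", "InterferenceBasis", function(object) {
  cat("InterferenceBasis:", nrow(object@components), "components x",
      ncol(object@components), "channels\n")
  cat("  explained variance:",
      paste(sprintf("%.3f", object@explainedVarianceRatio), collapse = " "),
      sprintf("(cumulative %.3f)\n", sum(object@explainedVarianceRatio)))
})

.emscColnames <- function(polyOrder, k) {
  c("offset",
    if (polyOrder > 0) paste0("poly", seq_len(polyOrder)),
    "reference",
    if (k > 0) paste0("interference", seq_len(k)))
}

#' Build an EMSC model from a dataset
#'
#' Assembles the extended multiplicative scatter correction design matrix
#' `[1, lambda, ..., lambda^p, r, g1, ..., gk]`, with the reference spectrum
#' `r` equal to the dataset column mean, `lambda` the wavenumber axis
#' affinely mapped to \eqn{[-1, 1]}, and `g_j` the interference component
#' spectra. The design is rank-checked; a collinear column (for instance an
#' interference component equal to the reference) raises an error naming it.
#'
#' @param x a [RamanSpectra-class] object.
#' @param polyOrder polynomial baseline order of the model (default 4).
#' @param interference an [InterferenceBasis-class], or `NULL` for plain MSC
#'   with polynomial terms only.
#' @param bMin smallest admissible magnitude of the reference coefficient.
#' @return an [EMSCModel-class].
#' @export
buildEMSCModel <- function(x, polyOrder = 4L, interference = NULL,
                           bMin = 1e-6) {
  wn <- wavenumbers(x)
  r <- rowMeans(intensityMatrix(x))
  if (is.null(interference))
    interference <- new("InterferenceBasis",
                        components = matrix(0, 0, length(wn)),
                        explainedVarianceRatio = numeric())
  if (ncol(interference@components) != length(wn))
    stop("interference components are not aligned to the dataset axis")
  lam <- .scaleAxis(wn)
  polyOrder <- as.integer(polyOrder)
  P <- if (polyOrder > 0) outer(lam, seq_len(polyOrder), `^`) else NULL
  X <- cbind(1, P, r, t(interference@components))
  colnames(X) <- .emscColnames(polyOrder, nrow(interference@components))
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  qrX <- qr(X)   # LINPACK: reliable rank + column pivoting
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: design matrix is rank deficient; ",
         "offending column(s): ", paste(bad, collapse = ", "))
  }
  new("EMSCModel", reference = r, polyOrder = polyOrder,
      interference = interference, wavenumber = wn, design = X,
      conditionNumber = cond, bMin = bMin)
}

setMethod("show", "EMSCModel", function(object) {
  cat("EMSCModel:", length(object@reference), "channels, polynomial order",
      object@polyOrder, "+", nrow(object@interference@components),
      "interference components\n")
  cat(sprintf("  design condition number: %.3g\n", object@conditionNumber))
})

.emscCoef <- function(Y, model) {
  # least squares of one or more spectra (columns of Y) on the design
  qr.coef(qr(model@design), Y)
}

#' Fit the EMSC model to one spectrum
#'
#' Ordinary least squares of the spectrum on the model design matrix.
#'
#' @param y numeric spectrum aligned to the model axis.
#' @param model an [EMSCModel-class].
#' @return an [EMSCFit-class] with offset `a`, polynomial coefficients `c`,
#'   reference coefficient `b`, interference coefficients `d` and residual
#'   `rmse`.
#' @export
fitEMSC <- function(y, model) {
  if (length(y) != length(model@reference))
    stop("spectrum is not aligned to the model axis")
  beta <- as.numeric(.emscCoef(cbind(y), model))
  names(beta) <- colnames(model@design)
  if (!all(is.finite(beta))) stop("fit error: non-finite EMSC coefficients")
  b <- beta[["reference"]]
  if (abs(b) <= model@bMin)
    stop("degenerate-fit error: |b| <= ", model@bMin,
         " (spectrum unrelated to reference)")
  p <- model@polyOrder
  k <- nrow(model@interference@components)
  resid <- y - as.numeric(model@design %*% beta)
  new("EMSCFit",
      a = beta[["offset"]],
      c = if (p > 0) unname(beta[paste0("poly", seq_len(p))]) else numeric(),
      b = b,
      d = if (k > 0) unname(beta[paste0("interference", seq_len(k))]) else numeric(),
      rmse = sqrt(mean(resid^2)))
}

setMethod("show", "EMSCFit", function(object) {
  cat(sprintf("EMSCFit: a=%.4g b=%.4g rmse=%.4g\n",
              object@a, object@b, object@rmse))
  if (length(object@c))
    cat("  poly c:", paste(sprintf("%.4g", object@c), collapse = " "), "\n")
  if (length(object@d))
    cat("  interference d:", paste(sprintf("%.4g", object@d), collapse = " "), "\n")
})

#' Apply an EMSC fit to correct a spectrum
#'
#' Subtracts the fitted offset, polynomial baseline and interference
#' contributions and divides by the reference coefficient:
#' \eqn{(s - a - \sum_i c_i \tilde\lambda^i - \sum_j d_j g_j)/b}. The
#' interference is thereby neutralized, not merely removed: its fitted share
#' is taken out before the multiplicative normalization.
#'
#' @param y the spectrum that was fitted.
#' @param fit the corresponding [EMSCFit-class].
#' @param model the [EMSCModel-class].
#' @return the corrected spectrum.
#' @export
correctSpectrum <- function(y, fit, model) {
  if (abs(fit@b) <= model@bMin)
    stop("degenerate-fit error: |b| <= ", model@bMin)
  p <- model@polyOrder
  k <- nrow(model@interference@components)
  contrib <- rep(fit@a, length(y))
  if (p > 0) {
    lam <- .scaleAxis(model@wavenumber)
    contrib <- contrib + outer(lam, seq_len(p), `^`) %*% fit@c
  }
  if (k > 0)
    contrib <- contrib + t(model@interference@components) %*% fit@d
  as.numeric((y - contrib) / fit@b)
}

#' EMSC-correct a whole dataset
#'
#' Fits and corrects every spectrum; spectra with a degenerate fit
#' (`|b| <= bMin`) are quarantined rather than aborting the run.
#'
#' @param x a [RamanSpectra-class] object aligned to the model axis.
#' @param model an [EMSCModel-class].
#' @return list with `spectra` (corrected `RamanSpectra`, quarantined columns
#'   dropped), `coefficients` (`data.frame`: spectrum_id, a, c..., b, d...,
#'   rmse) and `quarantine` (character vector of degenerate spectrum ids).
#' @export
correctSpectra <- function(x, model) {
  Y <- intensityMatrix(x)
  if (nrow(Y) != length(model@reference))
    stop("dataset is not aligned to the model axis")
  B <- .emscCoef(Y, model)                       # coefficients x spectra
  rownames(B) <- colnames(model@design)
  p <- model@polyOrder
  k <- nrow(model@interference@components)
  fitted_nonref <- model@design[, rownames(B) != "reference", drop = FALSE] %*%
    B[rownames(B) != "reference", , drop = FALSE]
  resid <- Y - model@design %*% B
  rmse <- sqrt(colMeans(resid^2))
  b <- B["reference", ]
  ok <- is.finite(b) & abs(b) > model@bMin
  corrected <- sweep(Y - fitted_nonref, 2, b, `/`)
  coefs <- data.frame(spectrum_id = colnames(Y), a = B["offset", ],
                      row.names = NULL)
  if (p > 0) for (i in seq_len(p)) coefs[[paste0("c", i)]] <- B[paste0("poly", i), ]
  coefs$b <- b
  if (k > 0) for (j in seq_len(k))
    coefs[[paste0("d", j)]] <- B[paste0("interference", j), ]
  coefs$rmse <- rmse
  out <- x[, ok]
  SummarizedExperiment::assay(out, "intensity") <- corrected[, ok, drop = FALSE]
  list(spectra = out, coefficients = coefs,
       quarantine = colnames(Y)[!ok])
}
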