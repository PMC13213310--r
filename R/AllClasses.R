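#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.TISSUE_CLASSES <- c("NA", "CAA")
.WEIGHT_CLASSES <- c("NW", "OW")

#' RamanSpectra: a container for hyperspectral Raman maps
#'
#' `RamanSpectra` extends [SummarizedExperiment::SummarizedExperiment] for
#' wavenumber-resolved Raman spectra. Rows are spectral channels (with the
#' wavenumber axis, in reciprocal centimetres, stored in `rowData`), columns
#' are individual spectra (map pixels), and per-spectrum metadata (sample id,
#' tissue class `NA`/`CAA`, weight class `NW`/`OW`, region-of-interest id and
#' map coordinates in micrometres) live in `colData`.
#'
#' @slot ... inherited from `SummarizedExperiment`; the single assay is named
#'   `"intensity"`.
#'
#' @details The validity method enforces: a strictly increasing, finite,
#' positive wavenumber axis of length at least 2; finite intensities; tissue
#' and weight classes drawn from the closed enums `{NA, CAA}` and `{NW, OW}`;
#' and no duplicated `(sample_id, roi_id, x_um, y_um)` tuples among spectra
#' whose coordinates are fully specified.
#'
#' @seealso [RamanSpectra()] for the constructor, [wavenumbers()],
#'   [intensityMatrix()], [spectrumMeta()] for accessors.
#' @export
setClass("RamanSpectra", contains = "SummarizedExperiment")

.META_COLS <- c("spectrum_id", "sample_id", "tissue_class", "weight_class",
                "roi_id", "x_um", "y_um")

setValidity("RamanSpectra", function(object) {
  msgs <- character()
  wn <- rowData(object)$wavenumber
  if (is.null(wn))
    return("rowData must contain a 'wavenumber' column")
  if (length(wn) < 2L)
    msgs <- c(msgs, "wavenumber axis must have length >= 2")
  if (!all(is.finite(wn)) || any(wn <= 0))
    msgs <- c(msgs, "wavenumbers must be finite and positive")
  if (any(diff(wn) <= 0))
    msgs <- c(msgs, "wavenumber axis must be strictly increasing")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'intensity' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "intensity"))))
    msgs <- c(msgs, "intensities must all be finite")
  cd <- colData(object)
  missing_cols <- setdiff(.META_COLS, colnames(cd))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("colData lacks columns: ",
                           paste(missing_cols, collapse = ", ")))
  else {
    tc <- cd$tissue_class
    if (!all(is.na(tc) | tc %in% .TISSUE_CLASSES))
      msgs <- c(msgs, "tissue_class values must be 'NA' or 'CAA'")
    wc <- cd$weight_class
    if (!all(is.na(wc) | wc %in% .WEIGHT_CLASSES))
      msgs <- c(msgs, "weight_class values must be 'NW' or 'OW'")
    key <- data.frame(s = cd$sample_id, r = cd$roi_id,
                      x = cd$x_um, y = cd$y_um)
    complete <- stats::complete.cases(key)
    if (any(duplicated(key[complete, , drop = FALSE])))
      msgs <- c(msgs, "duplicate (sample_id, roi_id, x_um, y_um) tuples")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RamanSpectra object
#'
#' @param wavenumber Numeric vector of channel wavenumbers (reciprocal
#'   centimetres), strictly increasing.
#' @param intensity Numeric matrix of intensities, channels in rows and
#'   spectra in columns (`length(wavenumber)` x `n_spectra`).
#' @param meta `data.frame` (or `DataFrame`) of per-spectrum metadata with one
#'   row per spectrum. Recognised columns: `spectrum_id`, `sample_id`,
#'   `tissue_class` (`"NA"`/`"CAA"`), `weight_class` (`"NW"`/`"OW"`),
#'   `roi_id`, `x_um`, `y_um`. Missing columns are filled with `NA`;
#'   `spectrum_id` defaults to the intensity column names or `S1..Sn`.
#'
#' @return A [RamanSpectra-class] object.
#' @examples
#' wn <- seq(900, 1800, by = 10)
#' y  <- matrix(rexp(length(wn) * 4), ncol = 4)
#' rs <- RamanSpectra(wn, y)
#' rs
#' @export
RamanSpectra <- function(wavenumber, intensity, meta = NULL) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(wavenumber))
    stop("intensity must have one row per wavenumber channel (",
         nrow(intensity), " rows vs ", length(wavenumber), " channels)")
  n <- ncol(intensity)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))[seq_len(n), ,
                                                                drop = FALSE]
  meta <- as.data.frame(meta)
  if (nrow(meta) != n)
    stop("meta must have one row per spectrum (", nrow(meta), " vs ", n, ")")
  if (is.null(meta$spectrum_id)) {
    meta$spectrum_id <- if (!is.null(colnames(intensity)))
      colnames(intensity) else paste0("S", seq_len(n))
  }
  for (cc in setdiff(.META_COLS, colnames(meta)))
    meta[[cc]] <- if (cc %in% c("x_um", "y_um")) NA_real_ else NA_character_
  meta <- meta[, union(.META_COLS, colnames(meta)), drop = FALSE]
  colnames(intensity) <- meta$spectrum_id
  se <- SummarizedExperiment(
    assays  = list(intensity = intensity),
    rowData = DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = DataFrame(meta, row.names = meta$spectrum_id))
  new("RamanSpectra", se)
}

#' Spectral region of interest on the wavenumber axis
#'
#' A closed wavenumber interval \eqn{[lo, hi]} used to cut spectra into the
#' fingerprint (default 900--1800 cm\eqn{^{-1}}) or high-wavenumber
#' (default 2700--3100 cm\eqn{^{-1}}) analysis windows, omitting the silent
#' region between them.
#'
#' @slot name region label, one of `"fingerprint"`, `"high_wavenumber"` or a
#'   custom label.
#' @slot lo,hi interval bounds in reciprocal centimetres, `lo < hi`.
#' @export
setClass("SpectralRegion",
         representation(name = "character", lo = "numeric", hi = "numeric"))

setValidity("SpectralRegion", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L ||
      !is.finite(object@lo) || !is.finite(object@hi))
    return("lo and hi must be single finite numbers")
  if (object@lo >= object@hi) return("lo must be < hi")
  TRUE
})

#' @describeIn SpectralRegion-class Constructor. With only `name` given, the
#'   standard analysis bounds are filled in: fingerprint (900, 1800),
#'   high_wavenumber (2700, 3100).
#' @param name,lo,hi see slots.
#' @export
spectralRegion <- function(name = c("fingerprint", "high_wavenumber"),
                           lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    name <- match.arg(name)
    bounds <- switch(name,
                     fingerprint = c(900, 1800),
                     high_wavenumber = c(2700, 3100))
    lo <- bounds[1]; hi <- bounds[2]
  }
  new("SpectralRegion", name = as.character(name)[1], lo = lo, hi = hi)
}

#' Orthonormal interference basis extracted by PCA
#'
#' Leading principal-component loadings of a (mean-centered) spectral dataset,
#' used as interference spectra in the EMSC design matrix to model carotenoid
#' resonance variability.
#'
#' @slot components k x n_channels matrix of orthonormal loading spectra.
#' @slot explainedVarianceRatio fraction of total variance per component,
#'   non-increasing.
#' @export
setClass("InterferenceBasis",
         representation(components = "matrix",
                        explainedVarianceRatio = "numeric"))

setValidity("InterferenceBasis", function(object) {
  k <- nrow(object@components)
  if (length(object@explainedVarianceRatio) != k)
    return("explainedVarianceRatio length must equal component count")
  evr <- object@explainedVarianceRatio
  if (any(diff(evr) > 1e-12)) return("explainedVarianceRatio must be non-increasing")
  if (sum(evr) > 1 + 1e-9) return("explainedVarianceRatio sums above 1")
  if (k > 0) {
    G <- object@components %*% t(object@components)
    if (max(abs(G - diag(k))) > 1e-8)
      return("components must be mutually orthonormal (tolerance 1e-8)")
  }
  TRUE
})

#' EMSC model: reference spectrum, polynomial basis and interference matrix
#'
#' Encodes the extended multiplicative scatter correction design
#' \deqn{s = a + \sum_{i=1}^{p} c_i \tilde\lambda^i + b\,r + \sum_j d_j g_j + e,}
#' where \eqn{r} is the reference spectrum (dataset mean),
#' \eqn{\tilde\lambda} the wavenumber axis affinely mapped to \eqn{[-1,1]},
#' and \eqn{g_j} PCA-derived interference spectra.
#'
#' @slot reference numeric reference spectrum (dataset column mean).
#' @slot polyOrder polynomial baseline order \eqn{p} (default 4).
#' @slot interference an [InterferenceBasis-class] (possibly with 0 components).
#' @slot wavenumber the wavenumber axis the model is aligned to.
#' @slot design the assembled design matrix (n_channels x (2 + p + k)).
#' @slot conditionNumber ratio of extreme singular values of the design.
#' @slot bMin smallest admissible magnitude of the reference coefficient b.
#' @export
setClass("EMSCModel",
         representation(reference = "numeric", polyOrder = "integer",
                        interference = "InterferenceBasis",
                        wavenumber = "numeric", design = "matrix",
                        conditionNumber = "numeric", bMin = "numeric"))

#' Per-spectrum EMSC fit
#'
#' Ordinary-least-squares coefficients of one spectrum on an
#' [EMSCModel-class] design: offset `a`, polynomial coefficients `c`,
#' multiplicative reference coefficient `b`, interference coefficients `d`,
#' and the residual root-mean-square error.
#'
#' @slot a,b numeric scalars.
#' @slot c,d numeric vectors (lengths p and k).
#' @slot rmse residual root-mean-square, non-negative.
#' @export
setClass("EMSCFit",
         representation(a = "numeric", c = "numeric", b = "numeric",
                        d = "numeric", rmse = "numeric"))

setValidity("EMSCFit", function(object) {
  if (!is.finite(object@b)) return("b must be finite")
  if (object@rmse < 0) return("rmse must be non-negative")
  TRUE
})

#' Ranked discriminant wavenumbers
#'
#' Per-channel random-forest importance scores (mean decrease in Gini
#' impurity, normalized to sum 1) mapped to wavenumbers and sorted by
#' decreasing importance, with cross-validated classifier accuracy attached.
#'
#' @slot wavenumbers wavenumbers in order of decreasing importance.
#' @slot importances matching non-negative scores, non-increasing, summing to 1.
#' @slot cvAccuracyMean,cvAccuracySd fold-accuracy statistics (`NA` when no
#'   cross-validation was run).
#' @export
setClass("FeatureRanking",
         representation(wavenumbers = "numeric", importances = "numeric",
                        cvAccuracyMean = "numeric", cvAccuracySd = "numeric"))

setValidity("FeatureRanking", function(object) {
  if (length(object@wavenumbers) != length(object@importances))
    return("wavenumbers and importances must have equal length")
  if (any(object@importances < 0)) return("importances must be non-negative")
  if (any(diff(object@importances) > 1e-12))
    return("importances must be sorted non-increasing")
  if (abs(sum(object@importances) - 1) > 1e-9)
    return("importances must sum to 1")
  TRUE
})

#' A 2-D embedding with stability and separability diagnostics
#'
#' @slot coords n x 2 matrix of embedding coordinates.
#' @slot seed the random seed that produced the retained embedding.
#' @slot stabilityDisparity mean symmetric Procrustes disparity to the
#'   sibling-seed embeddings (0 when all agree up to similarity transform).
#' @slot silhouette mean silhouette score of the labelled points on the
#'   embedding (`NA` when no labels were supplied).
#' @export
setClass("EmbeddingResult",
         representation(coords = "matrix", seed = "integer",
                        stabilityDisparity = "numeric", silhouette = "numeric"))

setValidity("EmbeddingResult", function(object) {
  if (ncol(object@coords) != 2L) return("coords must be n x 2")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@stabilityDisparity) == 1 &&
      !is.na(object@stabilityDisparity) && object@stabilityDisparity < 0)
    return("stabilityDisparity must be >= 0")
  s <- object@silhouette
  if (length(s) == 1 && !is.na(s) && (s < -1 || s > 1))
    return("silhouette must lie in [-1, 1]")
  TRUE
})
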