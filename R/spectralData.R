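#' @importFrom stats approx complete.cases sd prcomp rnorm runif var cor
#' @importFrom utils write.csv read.csv head packageVersion
NULL

#' @rdname RamanSpectra
#' @export
setMethod("wavenumbers", "RamanSpectra", function(object)
  as.numeric(rowData(object)$wavenumber))

#' @rdname RamanSpectra
#' @export
setMethod("intensityMatrix", "RamanSpectra", function(object)
  SummarizedExperiment::assay(object, "intensity"))

#' @rdname RamanSpectra
#' @export
setMethod("spectrumMeta", "RamanSpectra", function(object)
  as.data.frame(colData(object)))

setMethod("show", "RamanSpectra", function(object) {
  wn <- wavenumbers(object)
  cat("RamanSpectra with", length(wn), "channels x", ncol(object), "spectra\n")
  cat(sprintf("  wavenumber axis: %.1f .. %.1f cm-1\n", min(wn), max(wn)))
  tc <- table(colData(object)$tissue_class, useNA = "no")
  if (length(tc))
    cat("  tissue classes:", paste(names(tc), tc, sep = "=", collapse = " "), "\n")
  ns <- length(unique(stats::na.omit(colData(object)$sample_id)))
  if (ns) cat("  samples:", ns, "\n")
})

setMethod("show", "SpectralRegion", function(object) {
  cat(sprintf("SpectralRegion '%s': [%g, %g] cm-1\n",
              object@name, object@lo, object@hi))
})

#' Build the mapping grid of a rectangular region of interest
#'
#' Enumerates the motorized-stage positions of a rectangular Raman map,
#' borders inclusive, in row-major order (y varies slowest). A 30 um x 30 um
#' region at 1 um step yields the 31 x 31 = 961 pixels of a standard
#' adipocyte map.
#'
#' @param width_um,height_um extent of the region of interest in micrometres
#'   (non-negative, integer multiples of `step_um` within 1e-9).
#' @param step_um positive step size in micrometres.
#' @return `data.frame` with columns `x_um`, `y_um`, one row per position.
#' @examples
#' nrow(buildMapGrid(30, 30, 1))  # 961
#' @export
buildMapGrid <- function(width_um, height_um, step_um = 1) {
  if (!is.finite(step_um) || step_um <= 0)
    stop("invalid geometry: step_um must be positive")
  if (!is.finite(width_um) || !is.finite(height_um) ||
      width_um < 0 || height_um < 0)
    stop("invalid geometry: extents must be non-negative")
  nx <- width_um / step_um
  ny <- height_um / step_um
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("invalid geometry: extents must be integer multiples of step_um")
  xs <- seq(0, by = step_um, length.out = round(nx) + 1)
  ys <- seq(0, by = step_um, length.out = round(ny) + 1)
  data.frame(x_um = rep(xs, times = length(ys)),
             y_um = rep(ys, each = length(xs)))
}

#' Cut a dataset to a spectral region
#'
#' Restricts a [RamanSpectra-class] object to the channels inside the closed
#' interval of a [SpectralRegion-class] (e.g. fingerprint 900--1800 or
#' high-wavenumber 2700--3100 cm\eqn{^{-1}}), preserving channel order and
#' all per-spectrum metadata.
#'
#' @param x a `RamanSpectra` object.
#' @param region a `SpectralRegion` (or the name of a standard region).
#' @return the restricted `RamanSpectra`.
#' @export
setMethod("cutRegion", c("RamanSpectra", "SpectralRegion"),
  function(x, region) {
    wn <- wavenumbers(x)
    keep <- wn >= region@lo & wn <= region@hi
    if (!any(keep))
      stop("empty region: no channels inside [", region@lo, ", ", region@hi, "]")
    x[keep, ]
  })

#' @rdname cutRegion
#' @export
setMethod("cutRegion", c("RamanSpectra", "character"),
  function(x, region) cutRegion(x, spectralRegion(region)))

#' Resample datasets onto a common wavenumber axis and concatenate
#'
#' Linearly interpolates each spectrum of each input dataset onto `target`
#' and concatenates the results row-wise (spectra-wise) with merged
#' metadata. Every source axis must span the target axis; extrapolation is
#' refused.
#'
#' @param datasets list of [RamanSpectra-class] objects.
#' @param target numeric target wavenumber axis (strictly increasing).
#' @return one concatenated `RamanSpectra` on the `target` axis.
#' @export
resampleToCommonAxis <- function(datasets, target) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  target <- as.numeric(target)
  if (any(diff(target) <= 0)) stop("target axis must be strictly increasing")
  mats <- vector("list", length(datasets))
  metas <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    wn <- wavenumbers(ds)
    if (min(target) < min(wn) - 1e-12 || max(target) > max(wn) + 1e-12)
      stop("extrapolation error: target axis extends beyond source axis ",
           "of dataset ", i)
    Y <- intensityMatrix(ds)
    if (identical(wn, target)) {
      mats[[i]] <- Y
    } else {
      mats[[i]] <- apply(Y, 2, function(col)
        stats::approx(wn, col, xout = target, method = "linear")$y)
    }
    metas[[i]] <- spectrumMeta(ds)
  }
  meta <- do.call(rbind, metas)
  if (any(duplicated(meta$spectrum_id)))
    meta$spectrum_id <- make.unique(meta$spectrum_id, sep = "_")
  RamanSpectra(target, do.call(cbind, mats), meta)
}

#' Group-wise mean spectra
#'
#' Arithmetic mean intensity per channel, optionally per level of a metadata
#' column (e.g. `sample_id` or `tissue_class`) -- the per-sample mean-spectrum
#' comparison used to interpret embedding outliers.
#'
#' @param x a [RamanSpectra-class] object.
#' @param groupBy name of a `spectrumMeta(x)` column, or `NULL` for the
#'   grand mean.
#' @return named list of numeric mean spectra (single element `"all"` when
#'   `groupBy` is `NULL`).
#' @export
setMethod("meanSpectrum", "RamanSpectra", function(x, groupBy = NULL) {
  if (ncol(x) == 0L) stop("dataset is empty")
  Y <- intensityMatrix(x)
  if (is.null(groupBy)) return(list(all = rowMeans(Y)))
  meta <- spectrumMeta(x)
  if (!groupBy %in% colnames(meta))
    stop("unknown metadata field: ", groupBy)
  g <- as.character(meta[[groupBy]])
  out <- lapply(split(seq_along(g), g), function(idx)
    rowMeans(Y[, idx, drop = FALSE]))
  out
})

#' Parse a sample identifier of the form <weight><index>_<tissue>
#'
#' Sample names follow the `NW5_CAA` convention: weight class (`NW`/`OW`),
#' patient index, underscore, tissue class (`NA`/`CAA`).
#'
#' @param sample_id character vector of sample identifiers.
#' @return `data.frame` with columns `weight_class`, `patient_index`,
#'   `tissue_class` (`NA` where a name does not match the pattern).
#' @export
parseSampleId <- function(sample_id) {
  m <- regmatches(sample_id,
                  regexec("^(NW|OW)([0-9]+)_(NA|CAA)$", sample_id))
  out <- data.frame(weight_class = NA_character_,
                    patient_index = NA_integer_,
                    tissue_class = NA_character_,
                    row.names = NULL)[rep(1, length(sample_id)), , drop = FALSE]
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 4) {
      out$weight_class[i] <- m[[i]][2]
      out$patient_index[i] <- as.integer(m[[i]][3])
      out$tissue_class[i] <- m[[i]][4]
    }
  }
  rownames(out) <- NULL
  out
}

#' Read / write spectral matrices with companion metadata
#'
#' The on-disk format is a delimited text matrix whose first column
#' (`wavenumber_cm-1`) carries the axis and whose remaining columns carry one
#' spectrum each (header row = spectrum ids), plus a companion metadata CSV
#' with columns `spectrum_id`, `sample_id`, `tissue_class`, `weight_class`,
#' `roi_id`, `x_um`, `y_um`. The delimiter is auto-detected among tab, comma
#' and semicolon. Files with a descending axis are reversed on read (with a
#' notice); a non-monotone axis is an error. Intensities are written with 10
#' significant digits, so a write/read round trip preserves values to better
#' than 1e-9 relative and metadata labels exactly.
#'
#' @param path path of the spectral matrix file.
#' @param metaPath path of the metadata CSV (optional on read).
#' @param x a [RamanSpectra-class] object (for writing).
#' @return `readRamanSpectra` returns a `RamanSpectra`;
#'   `writeRamanSpectra` returns `invisible(c(path, metaPath))`.
#' @export
readRamanSpectra <- function(path, metaPath = NULL) {
  dt <- tryCatch(
    data.table::fread(path, sep = "auto", header = TRUE, fill = FALSE,
                      data.table = FALSE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) < 2) stop("format error: need a wavenumber column plus ",
                         "at least one spectrum column")
  wn <- as.numeric(dt[[1]])
  Y <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(Y) <- "double"
  d <- diff(wn)
  if (all(d < 0)) {
    message("wavenumber axis is descending; reversing on read")
    wn <- rev(wn); Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  } else if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop("non-monotone wavenumber axis at row ", bad + 1,
         " (", wn[bad], " -> ", wn[bad + 1], ")")
  }
  ids <- colnames(Y)
  meta <- NULL
  if (!is.null(metaPath)) {
    # the tissue class 'NA' (normal adipocyte) is a real label, not a
    # missing value: read everything as character, then coerce coordinates
    meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = "")
    for (cc in intersect(c("x_um", "y_um"), colnames(meta)))
      meta[[cc]] <- suppressWarnings(as.numeric(meta[[cc]]))
    if (!"spectrum_id" %in% colnames(meta))
      stop("metadata file lacks a spectrum_id column")
    missing_meta <- setdiff(ids, meta$spectrum_id)
    if (length(missing_meta))
      stop("metadata mismatch: no metadata row for spectrum column(s) ",
           paste(missing_meta, collapse = ", "))
    extra <- setdiff(meta$spectrum_id, ids)
    if (length(extra))
      stop("metadata mismatch: metadata row(s) without spectrum column: ",
           paste(extra, collapse = ", "))
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  }
  RamanSpectra(wn, Y, meta)
}

#' @rdname readRamanSpectra
#' @param sep field delimiter used when writing (default tab).
#' @export
writeRamanSpectra <- function(x, path, metaPath = NULL, sep = "\t") {
  wn <- wavenumbers(x)
  Y <- intensityMatrix(x)
  M <- cbind(signif(wn, 10), signif(Y, 10))
  colnames(M) <- c("wavenumber_cm-1", colnames(Y))
  utils::write.table(M, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(metaPath))
    utils::write.csv(spectrumMeta(x), metaPath, row.names = FALSE)
  invisible(c(path, metaPath))
}
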