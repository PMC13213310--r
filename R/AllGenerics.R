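#' @rdname RamanSpectra
#' @param object,x a [RamanSpectra-class] object.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname RamanSpectra
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname RamanSpectra
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))

#' @rdname cutRegion
#' @export
setGeneric("cutRegion", function(x, region) standardGeneric("cutRegion"))

#' @rdname meanSpectrum
#' @export
setGeneric("meanSpectrum", function(x, groupBy = NULL) standardGeneric("meanSpectrum"))
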