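#' Wavenumber axis of a spectral object
#' @param x a [RamanSpectra-class] object.
#' @return numeric vector of Raman shifts (cm^-1).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Regression targets of a spectral object
#' @param x a [RamanSpectra-class] object.
#' @return numeric vector, one value per spectrum (`NA` where unknown).
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname targets
#' @param value replacement targets.
#' @export
setGeneric("targets<-", function(x, value) standardGeneric("targets<-"))

#' Spectrum identifiers
#' @param x a [RamanSpectra-class] object.
#' @return character vector of labels.
#' @export
setGeneric("spectraIDs", function(x) standardGeneric("spectraIDs"))

#' Declared unit of the regression targets
#' @param x a [RamanSpectra-class] object.
#' @return character scalar, e.g. `"mmol/L"`.
#' @export
setGeneric("targetUnit", function(x) standardGeneric("targetUnit"))

#' Intensity matrix of a spectral object
#' @param x a [RamanSpectra-class] object.
#' @return numeric M x N matrix (wavenumbers x spectra).
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
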