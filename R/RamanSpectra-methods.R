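#' @describeIn RamanSpectra wavenumber axis (cm^-1).
#' @param x,object a `RamanSpectra` object.
#' @export
setMethod("wavenumbers", "RamanSpectra", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @describeIn RamanSpectra regression targets (NA where unknown).
#' @export
setMethod("targets", "RamanSpectra", function(x)
  as.numeric(SummarizedExperiment::colData(x)$target))

#' @describeIn RamanSpectra replace the regression targets.
#' @param value numeric replacement vector of length `ncol(x)`.
#' @export
setMethod("targets<-", "RamanSpectra", function(x, value) {
  if (length(value) != ncol(x))
    stop("replacement targets must have length ", ncol(x), call. = FALSE)
  SummarizedExperiment::colData(x)$target <- as.numeric(value)
  validObject(x)
  x
})

#' @describeIn RamanSpectra spectrum labels.
#' @export
setMethod("spectraIDs", "RamanSpectra", function(x)
  as.character(SummarizedExperiment::colData(x)$id))

#' @describeIn RamanSpectra declared target unit.
#' @export
setMethod("targetUnit", "RamanSpectra", function(x) {
  u <- S4Vectors::metadata(x)$unit
  if (is.null(u)) NA_character_ else u
})

#' @describeIn RamanSpectra the M x N intensity matrix.
#' @export
setMethod("intensityMatrix", "RamanSpectra", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @describeIn RamanSpectra compact display.
#' @export
setMethod("show", "RamanSpectra", function(object) {
  wn <- wavenumbers(object)
  tg <- targets(object)
  cat("RamanSpectra: ", nrow(object), " wavenumber points x ",
      ncol(object), " spectra\n", sep = "")
  if (length(wn))
    cat(sprintf("  range: %.1f-%.1f cm^-1\n", min(wn), max(wn)))
  known <- sum(!is.na(tg))
  if (known)
    cat(sprintf("  targets [%s]: %d known, %.3g-%.3g\n",
                targetUnit(object), known,
                min(tg, na.rm = TRUE), max(tg, na.rm = TRUE)))
  else cat("  targets: none\n")
  invisible(NULL)
})

# internal: spectra as rows (N x M), the orientation the model fitters use
.modelMatrix <- function(x) t(intensityMatrix(x))

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' Uses the conversion 1 mmol/L = 18.016 mg/dL (glucose molar mass
#' 180.16 g/mol).
#'
#' @param x numeric concentrations.
#' @param from,to `"mg/dL"` or `"mmol/L"`.
#' @return converted concentrations.
#' @examples
#' convertGlucoseUnits(82.8, "mg/dL", "mmol/L")  # ~4.6
#' @export
convertGlucoseUnits <- function(x, from = c("mg/dL", "mmol/L"),
                                to = c("mmol/L", "mg/dL")) {
  from <- match.arg(from, c("mg/dL", "mmol/L"))
  to <- match.arg(to, c("mmol/L", "mg/dL"))
  f <- 18.016
  if (from == to) x
  else if (from == "mg/dL") x / f
  else x * f
}
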