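# Readers/writers for the two spectral container formats: per-spectrum
# two-column delimited text files (plus a one-value-per-line targets file),
# and a single JSON matrix container holding the M x N intensity matrix,
# wavenumber vector and target vector.

.parseNumericLines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- lapply(seq_along(idx), function(i) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals))
      stop("parse error in '", basename(path), "' line ", ln,
           ": non-numeric token '", tok[which(is.na(vals))[1]], "'",
           call. = FALSE)
    vals
  })
  rows
}

.fileStem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Read a single two-column text spectrum
#'
#' The file must hold at least two numeric columns — by default
#' `(wavenumber, intensity)`; pass `columns = c("intensity", "wavenumber")`
#' for exports with the reverse order. Whitespace- or comma-delimited;
#' lines starting with `#` are ignored. Rows are sorted to an ascending
#' wavenumber axis.
#'
#' @param path path to the text file.
#' @param columns order of the two columns in the file.
#' @param id spectrum label; defaults to the file stem.
#' @return a one-spectrum [RamanSpectra-class] object (target `NA`).
#' @export
readTextSpectrum <- function(path, columns = c("wavenumber", "intensity"),
                             id = NULL) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  columns <- match.arg(paste(columns, collapse = ","),
                       c("wavenumber,intensity", "intensity,wavenumber"))
  rows <- .parseNumericLines(path)
  if (length(rows) < 3L)
    stop("'", basename(path), "': need at least 3 data rows", call. = FALSE)
  ncols <- vapply(rows, length, 1L)
  if (any(ncols < 2L))
    stop("'", basename(path), "': need at least 2 numeric columns",
         call. = FALSE)
  m <- do.call(rbind, lapply(rows, function(r) r[1:2]))
  if (columns == "intensity,wavenumber") m <- m[, 2:1, drop = FALSE]
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (anyDuplicated(m[, 1]))
    stop("'", basename(path), "': duplicate wavenumbers", call. = FALSE)
  if (is.null(id)) id <- .fileStem(path)
  RamanSpectra(m[, 1], matrix(m[, 2], ncol = 1), ids = id, unit = NA_character_)
}

#' Read a batch of text spectra plus a targets file
#'
#' All spectra must share an identical wavenumber grid. The targets file
#' holds one regression value per line, in the same order as `paths`.
#'
#' @param paths character vector of spectrum file paths.
#' @param targetsPath path to the targets text file.
#' @param columns column order passed to [readTextSpectrum()].
#' @param unit declared target unit.
#' @return a [RamanSpectra-class] dataset, one column per file, in path
#'   order.
#' @export
readSpectraBatch <- function(paths, targetsPath,
                             columns = c("wavenumber", "intensity"),
                             unit = "mmol/L") {
  if (length(paths) < 1L) stop("no spectrum files given", call. = FALSE)
  specs <- lapply(paths, readTextSpectrum, columns = columns)
  wn <- wavenumbers(specs[[1]])
  for (i in seq_along(specs)[-1]) {
    wi <- wavenumbers(specs[[i]])
    if (length(wi) != length(wn) || any(wi != wn))
      stop("wavenumber grid of '", basename(paths[i]),
           "' does not match '", basename(paths[1]), "'", call. = FALSE)
  }
  tg <- unlist(.parseNumericLines(targetsPath))
  if (length(tg) != length(paths))
    stop("targets file has ", length(tg), " values for ", length(paths),
         " spectra", call. = FALSE)
  ints <- do.call(cbind, lapply(specs, intensityMatrix))
  RamanSpectra(wn, ints, targets = tg,
               ids = vapply(paths, .fileStem, ""), unit = unit)
}

#' Read a JSON matrix container
#'
#' The container is a single JSON document with arrays `wavenumbers` (M),
#' `targets` (N) and `intensities` (M x N, as `{dim, data}` column-major),
#' plus optional `ids` and `unit` fields. Numbers are stored at full
#' precision so [writeSpectraContainer()] round-trips bit-exactly.
#'
#' @param path container file path.
#' @return a validated [RamanSpectra-class] object.
#' @export
readSpectraContainer <- function(path) {
  obj <- .readJSON(path)
  for (key in c("wavenumbers", "intensities", "targets"))
    if (is.null(obj[[key]]))
      stop("container '", basename(path), "' is missing required array '",
           key, "'", call. = FALSE)
  ints <- .unpackMatrix(obj$intensities)
  if (length(obj$wavenumbers) != nrow(ints))
    stop("container shape mismatch: ", length(obj$wavenumbers),
         " wavenumbers for ", nrow(ints), " intensity rows", call. = FALSE)
  if (length(obj$targets) != ncol(ints))
    stop("container shape mismatch: ", length(obj$targets),
         " targets for ", ncol(ints), " spectra", call. = FALSE)
  ids <- obj$ids
  if (!is.null(ids) && length(ids) != ncol(ints))
    stop("container shape mismatch: ids", call. = FALSE)
  RamanSpectra(obj$wavenumbers, ints, targets = obj$targets, ids = ids,
               unit = if (is.null(obj$unit)) NA_character_ else obj$unit)
}

#' Write a JSON matrix container
#'
#' @param x a [RamanSpectra-class] object with at least one spectrum.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectraContainer <- function(x, path) {
  stopifnot(is(x, "RamanSpectra"))
  if (ncol(x) < 1L)
    stop("refusing to write an empty dataset", call. = FALSE)
  .writeJSON(list(
    format = "ramanquant-spectra", version = 1,
    unit = targetUnit(x),
    wavenumbers = wavenumbers(x),
    ids = spectraIDs(x),
    targets = targets(x),
    intensities = .packMatrix(unname(intensityMatrix(x)))), path)
  invisible(path)
}
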