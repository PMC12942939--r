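# The preprocessing chain: crop -> interpolate -> median despike ->
# baseline correction (iterative polynomial or EMSC) -> Savitzky-Golay
# smoothing -> optional area normalization. Stages preserve the (M, N)
# pairing of spectra with targets; only the wavenumber axis may change
# (crop/interpolate).

.checkOddWindow <- function(w, name, m = Inf) {
  if (length(w) != 1L || is.na(w) || w < 3L || w %% 2L == 0L)
    stop(name, " must be an odd integer >= 3 (got ", w, ")", call. = FALSE)
  if (w > m)
    stop(name, " (", w, ") exceeds the number of grid points (", m, ")",
         call. = FALSE)
  invisible(as.integer(w))
}

#' Preprocessing configuration
#'
#' Bundles the ordered parameters of the preprocessing chain. Stages are
#' skipped when their parameter is `NULL` (crop, interpolation, despike,
#' smoothing) or `"none"` (baseline). All validation happens here, before
#' any computation.
#'
#' @param cropLo,cropHi closed crop interval in cm^-1, or `NULL` to skip.
#' @param targetGrid wavenumber grid to interpolate onto, or `NULL`.
#' @param despikeWindow odd median-filter width in points, or `NULL`.
#' @param baselineMethod `"polynomial"`, `"emsc"` or `"none"`.
#' @param polyDegree degree of the iterative polynomial baseline.
#' @param maxIter,tol iteration controls of the polynomial baseline.
#' @param emscDegree polynomial order of the EMSC additive terms.
#' @param sgWindow,sgOrder Savitzky-Golay window (odd) and fit order
#'   (`sgOrder < sgWindow`); `sgWindow = NULL` skips smoothing.
#' @param normalize apply area normalization as the final stage?
#' @return a validated `PreprocessConfig` list.
#' @export
preprocessConfig <- function(cropLo = NULL, cropHi = NULL, targetGrid = NULL,
                             despikeWindow = 5L,
                             baselineMethod = c("polynomial", "emsc", "none"),
                             polyDegree = 5L, maxIter = 200L, tol = 1e-4,
                             emscDegree = 2L, sgWindow = 11L, sgOrder = 3L,
                             normalize = FALSE) {
  baselineMethod <- match.arg(baselineMethod)
  if (xor(is.null(cropLo), is.null(cropHi)))
    stop("cropLo and cropHi must be given together", call. = FALSE)
  if (!is.null(cropLo) && cropLo >= cropHi)
    stop("cropLo must be < cropHi", call. = FALSE)
  if (!is.null(targetGrid) && any(diff(targetGrid) <= 0))
    stop("targetGrid must be strictly increasing", call. = FALSE)
  if (!is.null(despikeWindow)) .checkOddWindow(despikeWindow, "despikeWindow")
  if (polyDegree < 0 || emscDegree < 0)
    stop("polynomial degrees must be >= 0", call. = FALSE)
  if (!is.null(sgWindow)) {
    .checkOddWindow(sgWindow, "sgWindow")
    if (sgOrder >= sgWindow || sgOrder < 0)
      stop("sgOrder must satisfy 0 <= sgOrder < sgWindow", call. = FALSE)
  }
  structure(list(cropLo = cropLo, cropHi = cropHi, targetGrid = targetGrid,
                 despikeWindow = despikeWindow,
                 baselineMethod = baselineMethod,
                 polyDegree = as.integer(polyDegree),
                 maxIter = as.integer(maxIter), tol = tol,
                 emscDegree = as.integer(emscDegree),
                 sgWindow = sgWindow, sgOrder = as.integer(sgOrder),
                 normalize = isTRUE(normalize)),
            class = "PreprocessConfig")
}

.replaceIntensity <- function(x, m) {
  SummarizedExperiment::assay(x, "intensity") <- m
  validObject(x)
  x
}

#' Crop spectra to a wavenumber interval
#'
#' Retains exactly the grid points with `lo <= w <= hi` (closed interval);
#' targets are untouched.
#'
#' @param x a [RamanSpectra-class] object.
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return the cropped dataset.
#' @export
cropSpectra <- function(x, lo, hi) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  keep <- which(wavenumbers(x) >= lo & wavenumbers(x) <= hi)
  if (length(keep) < 3L)
    stop("crop interval [", lo, ", ", hi, "] retains ", length(keep),
         " points; need at least 3", call. = FALSE)
  x[keep, ]
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation of every spectrum onto `grid`, which must lie
#' within the current wavenumber span (no extrapolation).
#'
#' @param x a [RamanSpectra-class] object.
#' @param grid strictly increasing target wavenumbers (cm^-1).
#' @return the resampled dataset.
#' @export
interpolateToGrid <- function(x, grid) {
  wn <- wavenumbers(x)
  if (any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  if (min(grid) < min(wn) || max(grid) > max(wn))
    stop("grid [", min(grid), ", ", max(grid),
         "] extends beyond the data span [", min(wn), ", ", max(wn),
         "]; extrapolation is not supported", call. = FALSE)
  ints <- intensityMatrix(x)
  out <- apply(ints, 2, function(col) approx(wn, col, xout = grid)$y)
  out <- matrix(out, nrow = length(grid))
  RamanSpectra(grid, out, targets = targets(x), ids = spectraIDs(x),
               unit = targetUnit(x))
}

#' Remove cosmic-ray spikes with a running median
#'
#' Each intensity is replaced by the median of its centred window; the
#' edges use nearest-value padding.
#'
#' @param x a [RamanSpectra-class] object.
#' @param window odd window width in points (>= 3).
#' @return the despiked dataset.
#' @export
despikeMedian <- function(x, window = 5L) {
  m <- nrow(x)
  window <- .checkOddWindow(window, "despike window", m)
  h <- (window - 1L) %/% 2L
  ints <- intensityMatrix(x)
  out <- apply(ints, 2, function(col) {
    padded <- c(rep(col[1], h), col, rep(col[m], h))
    runmed(padded, window, endrule = "keep")[(h + 1L):(h + m)]
  })
  .replaceIntensity(x, matrix(out, nrow = m, dimnames = dimnames(ints)))
}

# one-vector iterative ("clip to fit") polynomial baseline; returns the
# fitted background
.polyBaselineVec <- function(y, Q, maxIter, tol, scale) {
  z <- y
  fit <- Q %*% crossprod(Q, z)
  for (it in seq_len(maxIter)) {
    z <- pmin(z, fit)
    newfit <- Q %*% crossprod(Q, z)
    if (max(abs(newfit - fit)) < tol * scale) {
      return(list(baseline = as.vector(newfit), converged = TRUE, iter = it))
    }
    fit <- newfit
  }
  list(baseline = as.vector(fit), converged = FALSE, iter = maxIter)
}

#' Iterative polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given degree, clips the working
#' spectrum to the pointwise minimum of itself and the fit, and refits
#' until the fitted background changes by less than `tol` (relative to the
#' intensity range) or `maxIter` is reached. The clipping keeps positive
#' peaks out of the background estimate, so peak heights survive the
#' subtraction. Non-convergence produces a warning, and the last iterate
#' is used.
#'
#' @param x a [RamanSpectra-class] object or a numeric intensity vector.
#' @param axis the wavenumber axis, used when `x` is a plain vector
#'   (defaults to the point index).
#' @param degree polynomial degree (>= 0).
#' @param maxIter,tol iteration controls.
#' @return object of the same kind as `x`, background subtracted.
#' @export
baselinePolynomial <- function(x, axis = NULL, degree = 5L,
                               maxIter = 200L, tol = 1e-4) {
  if (is(x, "RamanSpectra")) {
    wn <- wavenumbers(x)
    ints <- intensityMatrix(x)
  } else {
    wn <- if (is.null(axis)) seq_along(x) else axis
    ints <- matrix(as.numeric(x), ncol = 1)
  }
  m <- nrow(ints)
  if (m <= degree + 1L)
    stop("need more than degree + 1 points", call. = FALSE)
  basis <- cbind(1, if (degree >= 1L) stats::poly(wn, degree = degree))
  Q <- qr.Q(qr(basis))
  out <- ints
  nfail <- 0L
  for (j in seq_len(ncol(ints))) {
    scale <- diff(range(ints[, j]))
    if (scale == 0) scale <- max(abs(ints[, j]), 1)
    res <- .polyBaselineVec(ints[, j], Q, maxIter, tol, scale)
    if (!res$converged) nfail <- nfail + 1L
    out[, j] <- ints[, j] - res$baseline
  }
  if (nfail > 0L)
    warning(nfail, " spectrum/spectra did not converge within ", maxIter,
            " iterations; last iterate used", call. = FALSE)
  if (is(x, "RamanSpectra")) .replaceIntensity(x, out) else as.vector(out)
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Models each spectrum as `x = b * m + sum_k p_k * w^k + e` by least
#' squares against a reference spectrum `m` and polynomial terms in the
#' wavenumber axis normalized to \[-1, 1\]; the corrected spectrum is
#' `(x - sum_k p_k * w^k) / b`.
#'
#' @param x a [RamanSpectra-class] object.
#' @param reference `"mean"` (mean spectrum of `x`), a numeric vector on
#'   the same grid, or a one-spectrum `RamanSpectra`.
#' @param degree polynomial order of the additive terms (>= 0).
#' @return the corrected dataset.
#' @export
baselineEmsc <- function(x, reference = "mean", degree = 2L) {
  ints <- intensityMatrix(x)
  m <- nrow(ints)
  if (is.character(reference) && identical(reference, "mean")) {
    ref <- rowMeans(ints)
  } else if (is(reference, "RamanSpectra")) {
    if (nrow(reference) != m)
      stop("reference grid does not match", call. = FALSE)
    ref <- as.vector(intensityMatrix(reference)[, 1])
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != m)
      stop("reference grid does not match", call. = FALSE)
  }
  wn <- wavenumbers(x)
  w <- if (diff(range(wn)) > 0) 2 * (wn - min(wn)) / diff(range(wn)) - 1
       else rep(0, m)
  V <- vapply(0:degree, function(k) w^k, numeric(m))
  D <- cbind(ref, V)
  qrD <- qr(D)
  out <- ints
  for (j in seq_len(ncol(ints))) {
    cf <- qr.coef(qrD, ints[, j])
    cf[is.na(cf)] <- 0
    b <- cf[1]
    if (!is.finite(b) || b < 1e-8)
      stop("degenerate EMSC fit (b = ", format(b), ") for spectrum '",
           spectraIDs(x)[j], "'", call. = FALSE)
    out[, j] <- (ints[, j] - V %*% cf[-1]) / b
  }
  .replaceIntensity(x, out)
}

#' Savitzky-Golay smoothing
#'
#' Applies the central Savitzky-Golay convolution weights (local
#' least-squares polynomial of the given order) to every spectrum; the
#' edges are handled by mirror padding. Polynomial trends up to `order`
#' pass through unchanged in the interior.
#'
#' @param x a [RamanSpectra-class] object.
#' @param window odd window width, `window > order`.
#' @param order polynomial fit order.
#' @return the smoothed dataset.
#' @export
smoothSavitzkyGolay <- function(x, window = 11L, order = 3L) {
  m <- nrow(x)
  window <- .checkOddWindow(window, "SG window", m)
  if (order >= window || order < 0)
    stop("SG order must satisfy 0 <= order < window", call. = FALSE)
  h <- (window - 1L) %/% 2L
  coefs <- signal::sgolay(p = order, n = window)[h + 1L, ]
  ints <- intensityMatrix(x)
  # mirror padding (reflection about the edge point, edge excluded)
  padded <- rbind(ints[(h + 1L):2L, , drop = FALSE],
                  ints,
                  ints[(m - 1L):(m - h), , drop = FALSE])
  out <- matrix(0, m, ncol(ints), dimnames = dimnames(ints))
  for (o in 0:(2L * h))
    out <- out + coefs[o + 1L] * padded[(1L + o):(m + o), , drop = FALSE]
  .replaceIntensity(x, out)
}

#' Area normalization
#'
#' Divides each spectrum by the sum of its intensities so that each
#' spectrum sums to exactly 1. Idempotent.
#'
#' @param x a [RamanSpectra-class] object.
#' @return the normalized dataset.
#' @export
normalizeArea <- function(x) {
  ints <- intensityMatrix(x)
  s <- colSums(ints)
  if (any(s == 0))
    stop("cannot area-normalize zero-sum spectrum '",
         spectraIDs(x)[which(s == 0)[1]], "'", call. = FALSE)
  .replaceIntensity(x, sweep(ints, 2, s, "/"))
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: crop, interpolation onto a target grid, median
#' despiking, baseline correction, Savitzky-Golay smoothing, and optional
#' area normalization — skipping any stage whose configuration is absent.
#' Returns the processed dataset together with a per-stage report.
#'
#' @param x a [RamanSpectra-class] object.
#' @param config a [preprocessConfig()] object.
#' @return list with elements `dataset` (processed [RamanSpectra-class])
#'   and `report` (data.frame of executed stages, in order, with
#'   parameter strings).
#' @export
runPreprocessChain <- function(x, config = preprocessConfig()) {
  if (!inherits(config, "PreprocessConfig"))
    config <- do.call(preprocessConfig, config)
  stages <- character(0); params <- character(0)
  note <- function(stage, param) {
    stages <<- c(stages, stage); params <<- c(params, param)
  }
  if (!is.null(config$cropLo)) {
    x <- cropSpectra(x, config$cropLo, config$cropHi)
    note("crop", sprintf("[%g, %g] cm^-1 -> %d points",
                         config$cropLo, config$cropHi, nrow(x)))
  }
  if (!is.null(config$targetGrid)) {
    x <- interpolateToGrid(x, config$targetGrid)
    note("interpolate", sprintf("%d-point grid", nrow(x)))
  }
  if (!is.null(config$despikeWindow)) {
    before <- intensityMatrix(x)
    x <- despikeMedian(x, config$despikeWindow)
    note("despike", sprintf("window %d, %d points altered",
                            config$despikeWindow,
                            sum(intensityMatrix(x) != before)))
  }
  if (config$baselineMethod == "polynomial") {
    x <- baselinePolynomial(x, degree = config$polyDegree,
                            maxIter = config$maxIter, tol = config$tol)
    note("baseline", sprintf("polynomial degree %d", config$polyDegree))
  } else if (config$baselineMethod == "emsc") {
    x <- baselineEmsc(x, degree = config$emscDegree)
    note("baseline", sprintf("EMSC degree %d", config$emscDegree))
  }
  if (!is.null(config$sgWindow)) {
    x <- smoothSavitzkyGolay(x, config$sgWindow, config$sgOrder)
    note("smooth", sprintf("Savitzky-Golay window %d order %d",
                           config$sgWindow, config$sgOrder))
  }
  if (config$normalize) {
    x <- normalizeArea(x)
    note("normalize", "area (sum = 1)")
  }
  list(dataset = x,
       report = data.frame(stage = stages, parameters = params,
                           stringsAsFactors = FALSE))
}
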