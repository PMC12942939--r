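#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx predict rnorm runif rpois sd setNames runmed poly
#' @importFrom utils tail modifyList
NULL

#' RamanSpectra: a set of Raman spectra with regression targets
#'
#' `RamanSpectra` is the package's universal interchange object. It extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay named
#' `"intensity"` holding the M x N spectral intensity matrix (one column per
#' spectrum, in arbitrary detector units), the M Raman shifts (cm^-1) in
#' `rowData(x)$wavenumber`, and per-spectrum regression targets (e.g. blood
#' glucose) plus text ids in `colData`. The declared target unit (for glucose
#' normally `"mmol/L"` or `"mg/dL"`) is kept in `metadata(x)$unit`.
#'
#' Validity requires a strictly increasing, finite wavenumber axis, finite
#' intensities, and targets of length N (targets may be `NA` for data that is
#' to be predicted rather than used for calibration). An invalid object can
#' never be constructed.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [RamanSpectra()], [wavenumbers()], [targets()], [spectraIDs()]
#' @export
setClass("RamanSpectra", contains = "SummarizedExperiment")

.validRamanSpectra <- function(object) {
  msg <- character(0)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    if (anyNA(wn) || !all(is.finite(wn)))
      msg <- c(msg, "wavenumbers must be finite")
    if (length(wn) > 1L && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"target" %in% names(cd))
    msg <- c(msg, "colData column 'target' is required")
  if (!"id" %in% names(cd))
    msg <- c(msg, "colData column 'id' is required")
  if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(a) || !all(is.finite(a)))
      msg <- c(msg, "intensities must be finite")
  }
  if (length(msg)) msg else TRUE
}

setValidity("RamanSpectra", .validRamanSpectra)

#' Construct a RamanSpectra object
#'
#' @param wavenumbers numeric vector of M Raman shifts (cm^-1), strictly
#'   increasing.
#' @param intensities numeric M x N matrix, one spectrum per column.
#' @param targets numeric vector of N regression targets; `NA` allowed
#'   (default all `NA`).
#' @param ids character vector of N spectrum labels (default `"s1"..."sN"`).
#' @param unit declared unit of the targets, e.g. `"mmol/L"`.
#' @return A validated [RamanSpectra-class] object.
#' @examples
#' rs <- RamanSpectra(800:810, matrix(runif(22), 11, 2), targets = c(5, 6))
#' rs
#' @export
RamanSpectra <- function(wavenumbers, intensities, targets = NULL,
                         ids = NULL, unit = "mmol/L") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- ncol(intensities)
  if (is.null(targets)) targets <- rep(NA_real_, n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (length(targets) != n)
    stop("targets (", length(targets), ") must have one value per spectrum (",
         n, ")", call. = FALSE)
  if (length(ids) != n)
    stop("ids must have one label per spectrum", call. = FALSE)
  if (length(wavenumbers) != nrow(intensities))
    stop("wavenumbers (", length(wavenumbers),
         ") must match rows of the intensity matrix (", nrow(intensities), ")",
         call. = FALSE)
  colnames(intensities) <- as.character(ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(target = as.numeric(targets),
                                   id = as.character(ids),
                                   row.names = as.character(ids)),
    metadata = list(unit = unit))
  new("RamanSpectra", se)
}

#' Virtual parent of all fitted regression models
#'
#' Every fitted regressor (PLSR, SVR, MLP, CNN) carries the preprocessing
#' configuration it was trained behind (`preprocess`, possibly empty) so that
#' raw spectra presented at prediction time can be pushed through the same
#' chain, plus the declared target `unit`.
#'
#' @slot preprocess list; the [preprocessConfig()] provenance (may be empty).
#' @slot unit character; target unit label.
#' @export
setClass("RamanModel", representation("VIRTUAL",
  preprocess = "list", unit = "character"))

#' Fitted NIPALS partial least squares regression model
#'
#' @slot ncomp number of latent variables retained.
#' @slot xMean,yMean centering applied before deflation.
#' @slot coefficients regression vector B mapping centered X to centered y.
#' @slot weights,loadings,yloadings NIPALS W, P (M x A) and q (A) retained
#'   for inspection.
#' @export
setClass("PLSRModel", contains = "RamanModel", representation(
  ncomp = "integer", xMean = "numeric", yMean = "numeric",
  coefficients = "numeric", weights = "matrix", loadings = "matrix",
  yloadings = "numeric"))

#' Fitted epsilon-support-vector regression model
#'
#' Dual-form model `g(x) = sum_i a_i k(sv_i, x) + b` on internally
#' standardized features; `|a_i| <= C` for every support vector.
#'
#' @slot kernel `"linear"` or `"gaussian"`.
#' @slot cost,epsilon,gamma hyperparameters (gamma used by the Gaussian
#'   kernel only).
#' @slot supportVectors support vectors on the standardized feature scale.
#' @slot dualCoefs dual coefficients a_i (alpha_i - alpha_i^*).
#' @slot bias intercept b.
#' @slot svIndex training-row index of each support vector.
#' @slot xCenter,xScale feature standardization parameters.
#' @export
setClass("SVRModel", contains = "RamanModel", representation(
  kernel = "character", cost = "numeric", epsilon = "numeric",
  gamma = "numeric", supportVectors = "matrix", dualCoefs = "numeric",
  bias = "numeric", svIndex = "integer",
  xCenter = "numeric", xScale = "numeric"))

#' Fitted one-hidden-layer perceptron (tansig hidden, purelin output)
#'
#' Forward pass on min-max scaled input: `purelin(W2 %*% tansig(W1 %*% x + b1)
#' + b2)`, with the prediction mapped back to target units.
#'
#' @slot W1,b1 hidden layer weights (H x M) and biases.
#' @slot W2,b2 output layer weights (1 x H) and bias.
#' @slot xMin,xMax,yMin,yMax min-max scaling parameters to \[-1, 1\].
#' @slot trainLog per-epoch training MSE (scaled units).
#' @slot spec the training specification used.
#' @export
setClass("MLPModel", contains = "RamanModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  xMin = "numeric", xMax = "numeric", yMin = "numeric", yMax = "numeric",
  trainLog = "numeric", spec = "list"))

#' Fitted one-dimensional convolutional network regressor
#'
#' Four (by default) blocks of same-padded cross-correlation + ReLU + max
#' pooling, a ReLU dense layer on the flattened features, and a single linear
#' output neuron.
#'
#' @slot inputLength expected number of wavenumber points M.
#' @slot blocks list of per-block parameter sets (`W` kernel array
#'   k x Cin x Cout, `b` biases, `pool` width).
#' @slot Wd,bd,Wo,bo dense and output layer parameters (empty until fitted).
#' @slot xMin,xMax,yMin,yMax min-max scaling parameters.
#' @slot trainLog per-step training loss (scaled units).
#' @slot spec architecture + training specification.
#' @export
setClass("CNNModel", contains = "RamanModel", representation(
  inputLength = "integer", blocks = "list",
  Wd = "matrix", bd = "numeric", Wo = "matrix", bo = "numeric",
  xMin = "numeric", xMax = "numeric", yMin = "numeric", yMax = "numeric",
  trainLog = "numeric", spec = "list"))

#' Six-statistic regression evaluation report
#'
#' Holds the sum of squared errors, mean squared error, root mean squared
#' error, mean absolute error, coefficient of determination and Pearson
#' correlation between observed and predicted targets for one data partition.
#' `R2` may be negative (predictor worse than the mean); `COR` is `NA` when
#' either variance term is zero.
#'
#' @slot n sample count.
#' @slot SSE,MSE,RMSE,MAE error statistics (target units; SSE/MSE squared).
#' @slot R2 coefficient of determination.
#' @slot COR Pearson correlation.
#' @slot partition `"train"`, `"test"` or `"prediction"`.
#' @seealso [computeMetrics()], [evaluateModel()]
#' @export
setClass("EvaluationReport", representation(
  n = "integer", SSE = "numeric", MSE = "numeric", RMSE = "numeric",
  MAE = "numeric", R2 = "numeric", COR = "numeric", partition = "character"))
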