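# Model persistence: a single self-describing JSON archive per model
# (family tag, format version, shapes, numeric payload at full
# precision, preprocessing provenance). No executable code is
# serialized; loading an archive reconstructs a model that predicts
# identically to the saved one.

.ARCHIVE_FORMAT <- "ramanquant-model"
.ARCHIVE_VERSION <- 1L

.preprocessToList <- function(p) {
  if (inherits(p, "PreprocessConfig")) unclass(p) else p
}

.modelPayload <- function(model) {
  switch(class(model),
    PLSRModel = list(
      ncomp = model@ncomp, xMean = model@xMean, yMean = model@yMean,
      coefficients = model@coefficients,
      weights = .packMatrix(model@weights),
      loadings = .packMatrix(model@loadings),
      yloadings = model@yloadings),
    SVRModel = list(
      kernel = model@kernel, cost = model@cost, epsilon = model@epsilon,
      gamma = model@gamma,
      supportVectors = .packMatrix(model@supportVectors),
      dualCoefs = model@dualCoefs, bias = model@bias,
      svIndex = model@svIndex,
      xCenter = model@xCenter, xScale = model@xScale),
    MLPModel = list(
      W1 = .packMatrix(model@W1), b1 = model@b1,
      W2 = .packMatrix(model@W2), b2 = model@b2,
      xMin = model@xMin, xMax = model@xMax,
      yMin = model@yMin, yMax = model@yMax,
      trainLog = model@trainLog,
      spec = model@spec[c("hidden", "epochs", "learningRate", "lossGoal",
                          "seed")]),
    CNNModel = list(
      inputLength = model@inputLength,
      blocks = lapply(model@blocks, function(bl)
        list(W = .packArray(bl$W), b = bl$b, pool = bl$pool)),
      Wd = .packMatrix(model@Wd), bd = model@bd,
      Wo = .packMatrix(model@Wo), bo = model@bo,
      xMin = model@xMin, xMax = model@xMax,
      yMin = model@yMin, yMax = model@yMax,
      trainLog = model@trainLog,
      spec = model@spec[c("filters", "kernelWidth", "poolWidth",
                          "denseUnits", "featureLength", "iterations",
                          "learningRate", "batchSize", "seed")]),
    stop("unsupported model class: ", class(model), call. = FALSE))
}

.modelFamily <- function(model) {
  switch(class(model), PLSRModel = "plsr", SVRModel = "svr",
         MLPModel = "mlp", CNNModel = "cnn",
         stop("unsupported model class: ", class(model), call. = FALSE))
}

#' Save a fitted model to a JSON archive
#'
#' @param model a fitted PLSR, SVR, MLP or CNN model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  if (!is(model, "RamanModel"))
    stop("not a RamanQuant model", call. = FALSE)
  .writeJSON(list(
    format = .ARCHIVE_FORMAT, version = .ARCHIVE_VERSION,
    family = .modelFamily(model),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    unit = model@unit,
    preprocess = .preprocessToList(model@preprocess),
    payload = .modelPayload(model)), path)
  invisible(path)
}

#' Load a fitted model from a JSON archive
#'
#' Verifies the format tag, version and family before reconstructing the
#' model; the loaded model predicts identically to the saved one.
#'
#' @param path archive file path.
#' @return the reconstructed model object.
#' @export
loadModel <- function(path) {
  a <- .readJSON(path)
  if (!identical(a$format, .ARCHIVE_FORMAT))
    stop("'", path, "' is not a ", .ARCHIVE_FORMAT, " archive",
         call. = FALSE)
  if (!identical(as.integer(a$version), .ARCHIVE_VERSION))
    stop("archive version ", a$version, " is incompatible with this ",
         "package (expects ", .ARCHIVE_VERSION, ")", call. = FALSE)
  pp <- if (is.null(a$preprocess)) list() else a$preprocess
  unit <- if (is.null(a$unit)) NA_character_ else a$unit
  p <- a$payload
  model <- switch(as.character(a$family),
    plsr = new("PLSRModel", ncomp = as.integer(p$ncomp), xMean = p$xMean,
               yMean = p$yMean, coefficients = p$coefficients,
               weights = .unpackMatrix(p$weights),
               loadings = .unpackMatrix(p$loadings),
               yloadings = p$yloadings,
               preprocess = pp, unit = unit),
    svr = new("SVRModel", kernel = p$kernel, cost = p$cost,
              epsilon = p$epsilon,
              gamma = if (is.null(p$gamma)) NA_real_ else p$gamma,
              supportVectors = .unpackMatrix(p$supportVectors),
              dualCoefs = if (is.null(p$dualCoefs)) numeric(0)
                          else p$dualCoefs,
              bias = p$bias,
              svIndex = if (is.null(p$svIndex)) integer(0)
                        else as.integer(p$svIndex),
              xCenter = p$xCenter, xScale = p$xScale,
              preprocess = pp, unit = unit),
    mlp = new("MLPModel", W1 = .unpackMatrix(p$W1), b1 = p$b1,
              W2 = .unpackMatrix(p$W2), b2 = p$b2,
              xMin = p$xMin, xMax = p$xMax, yMin = p$yMin, yMax = p$yMax,
              trainLog = if (is.null(p$trainLog)) numeric(0) else p$trainLog,
              spec = p$spec, preprocess = pp, unit = unit),
    cnn = {
      m <- new("CNNModel", inputLength = as.integer(p$inputLength),
               blocks = lapply(p$blocks, function(bl)
                 list(W = .unpackArray(bl$W), b = bl$b,
                      pool = as.integer(bl$pool))),
               Wd = .unpackMatrix(p$Wd), bd = p$bd,
               Wo = .unpackMatrix(p$Wo), bo = p$bo,
               xMin = p$xMin, xMax = p$xMax, yMin = p$yMin, yMax = p$yMax,
               trainLog = if (is.null(p$trainLog)) numeric(0)
                          else p$trainLog,
               spec = p$spec, preprocess = pp, unit = unit)
      m@spec$filters <- as.integer(m@spec$filters)
      m@spec$featureLength <- as.integer(m@spec$featureLength)
      m
    },
    stop("unknown model family '", a$family, "' in archive", call. = FALSE))
  model
}
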