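# Config-driven orchestration of the end-to-end workflow:
# load/simulate -> preprocess -> split -> augment (train only) ->
# train -> evaluate -> save. A run configuration is a named list (or a
# YAML file with the same block keys): `input` or `simulate`,
# `preprocess`, `split`, `augment`, `model`, `outdir`, `seed`. The
# global seed is propagated deterministically to every stochastic stage
# (simulate: seed, split: seed+1, augment: seed+2, model: seed+3)
# unless a block sets its own. Seeded runs are byte-reproducible in
# their JSON reports.

.loadRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

.resolveSeeds <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$seed <- seed
  if (is.null(config$simulate$seed) && !is.null(config$simulate))
    config$simulate$seed <- seed
  if (is.null(config$split$seed)) config$split$seed <- seed + 1L
  if (is.null(config$augment$seed) && !is.null(config$augment))
    config$augment$seed <- seed + 2L
  if (!is.null(config$model) && is.null(config$model$seed))
    config$model$seed <- seed + 3L
  config
}

.loadInputData <- function(config) {
  if (!is.null(config$input$container))
    return(readSpectraContainer(config$input$container))
  if (!is.null(config$input$spectra))
    return(readSpectraBatch(config$input$spectra, config$input$targets))
  if (!is.null(config$simulate) || is.null(config$input)) {
    block <- if (is.null(config$simulate)) list(seed = config$seed)
             else config$simulate
    return(simulateNailfold(do.call(simConfig, block))$curated)
  }
  stop("config must provide an 'input' or 'simulate' block", call. = FALSE)
}

.checkModelBlock <- function(model) {
  if (is.null(model$family))
    stop("config error: model$family is required", call. = FALSE)
  if (length(model$family) != 1L)
    stop("config error: exactly one model family per run (got ",
         length(model$family), ")", call. = FALSE)
  match.arg(model$family, c("plsr", "svr", "mlp", "cnn"))
}

.modelInputLength <- function(model) {
  switch(class(model),
         PLSRModel = length(model@xMean),
         SVRModel = length(model@xCenter),
         MLPModel = length(model@xMin),
         CNNModel = model@inputLength)
}

.trainFamily <- function(family, train, block) {
  opts <- block[setdiff(names(block), "family")]
  switch(family,
    plsr = {
      kFolds <- if (is.null(opts$kFolds)) 5L else opts$kFolds
      ncomp <- opts$ncomp
      if (is.null(ncomp))
        ncomp <- selectPlsrComponents(train, kFolds = kFolds,
                                      maxComponents = opts$maxComponents,
                                      seed = opts$seed)$ncomp
      fitPlsr(train, ncomp = ncomp)
    },
    svr = {
      kernel <- if (is.null(opts$kernel)) "gaussian" else opts$kernel
      if (isTRUE(opts$gridSearch)) {
        gs <- gridSearchSvr(train, kernel = kernel,
                            grids = if (is.null(opts$grids)) list()
                                    else opts$grids,
                            kFolds = if (is.null(opts$kFolds)) 5L
                                     else opts$kFolds,
                            seed = opts$seed)
        fitSvr(train, kernel = kernel, cost = gs$best$cost,
               epsilon = gs$best$epsilon, gamma = gs$best$gamma)
      } else {
        fitSvr(train, kernel = kernel,
               cost = if (is.null(opts$cost)) 1 else opts$cost,
               epsilon = if (is.null(opts$epsilon)) 0.1 else opts$epsilon,
               gamma = opts$gamma)
      }
    },
    mlp = fitMlp(train, do.call(mlpTrainSpec,
                                opts[intersect(names(opts),
                                               names(formals(mlpTrainSpec)))])),
    cnn = fitCnn(train, do.call(cnnTrainSpec,
                                opts[intersect(names(opts),
                                               names(formals(cnnTrainSpec)))])))
}

#' Run the full training workflow from a configuration
#'
#' Loads (or simulates) a dataset, preprocesses it, splits it into
#' train/test/prediction partitions, optionally augments the training
#' partition, trains the configured model family, evaluates it on the
#' train and test partitions, and writes all artifacts to the output
#' directory: `model.json` (archive with preprocessing provenance),
#' `report_train.json` / `report_test.json`, `reports.txt`,
#' `prediction_raw.json` (the held-out raw spectra, for
#' [cmdPredict()]), `resolved_config.yaml`, and for the neural
#' families a `training_log.csv` of per-step losses.
#'
#' @param config a named list or path to a YAML file; blocks `input`
#'   (container path or text batch) or `simulate`, `preprocess`,
#'   `split`, `augment` (optional), `model` (with `family` = one of
#'   plsr/svr/mlp/cnn), `outdir`, `seed`.
#' @return (invisibly) list with the fitted model, the partitions, the
#'   train/test reports and the written file paths.
#' @export
cmdTrain <- function(config) {
  config <- .resolveSeeds(.loadRunConfig(config))
  family <- .checkModelBlock(config$model)
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  raw <- .loadInputData(config)
  ppCfg <- do.call(preprocessConfig,
                   if (is.null(config$preprocess)) list()
                   else config$preprocess)
  processed <- runPreprocessChain(raw, ppCfg)$dataset
  parts <- splitDataset(processed,
                        do.call(splitSpec,
                                if (is.null(config$split)) list()
                                else config$split))
  train <- parts$train
  if (!is.null(config$augment))
    train <- augmentStdShift(train, do.call(augmentSpec, config$augment))
  model <- .trainFamily(family, train, config$model)
  model@preprocess <- unclass(ppCfg)
  model@unit <- targetUnit(raw)
  repTrain <- evaluateModel(model, train, "train")
  repTest <- evaluateModel(model, parts$test, "test")
  paths <- list(model = file.path(outdir, "model.json"),
                reportTrain = file.path(outdir, "report_train.json"),
                reportTest = file.path(outdir, "report_test.json"),
                reportsTxt = file.path(outdir, "reports.txt"),
                predictionRaw = file.path(outdir, "prediction_raw.json"),
                config = file.path(outdir, "resolved_config.yaml"))
  saveModel(model, paths$model)
  writeReport(repTrain, paths$reportTrain)
  writeReport(repTest, paths$reportTest)
  writeLines(formatReport(repTrain, repTest), paths$reportsTxt)
  writeSpectraContainer(raw[, spectraIDs(parts$prediction)],
                        paths$predictionRaw)
  yaml::write_yaml(config, paths$config)
  if (is(model, "MLPModel") || is(model, "CNNModel")) {
    paths$trainingLog <- file.path(outdir, "training_log.csv")
    writeLines(c("step,loss",
                 sprintf("%d,%.17g", seq_along(model@trainLog),
                         model@trainLog)), paths$trainingLog)
  }
  invisible(list(model = model, partitions = parts,
                 reports = list(train = repTrain, test = repTest),
                 paths = paths))
}

#' Predict from a saved model archive
#'
#' Loads the archive, applies its recorded preprocessing configuration
#' to the raw input spectra, verifies grid compatibility, and writes
#' one prediction per spectrum to `predictions.txt` in `outdir`; when
#' targets are available (a targets file, or target values in the
#' container) an evaluation report is written as well.
#'
#' @param modelPath path to a [saveModel()] archive.
#' @param dataPath path to a spectra container of raw spectra.
#' @param targetsPath optional one-value-per-line targets file.
#' @param outdir output directory (default `"."`).
#' @return (invisibly) list with `predictions`, optional `report`, and
#'   the written paths.
#' @export
cmdPredict <- function(modelPath, dataPath, targetsPath = NULL,
                       outdir = ".") {
  model <- loadModel(modelPath)
  data <- readSpectraContainer(dataPath)
  if (length(model@preprocess))
    data <- runPreprocessChain(data,
                               do.call(preprocessConfig,
                                       model@preprocess))$dataset
  expected <- .modelInputLength(model)
  if (nrow(data) != expected)
    stop("data (", nrow(data), " points after preprocessing) is not ",
         "compatible with the model (expects ", expected,
         " points); check the wavenumber grid", call. = FALSE)
  preds <- predict(model, data)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(predictions = file.path(outdir, "predictions.txt"))
  writeLines(sprintf("%s\t%.17g", spectraIDs(data), preds),
             paths$predictions)
  report <- NULL
  y <- if (!is.null(targetsPath)) unlist(.parseNumericLines(targetsPath))
       else targets(data)
  if (!anyNA(y)) {
    report <- computeMetrics(y, preds, "prediction")
    paths$report <- file.path(outdir, "report_prediction.json")
    writeReport(report, paths$report)
  }
  invisible(list(predictions = preds, report = report, paths = paths))
}

#' Generate and write a synthetic dataset
#'
#' Writes `dataset_raw.json` and `dataset_curated.json` spectra
#' containers plus a `ground_truth.json` sidecar (signal, background,
#' spike and noise components, concentrations, curated index).
#'
#' @param config a named list or YAML path with an optional `simulate`
#'   block of [simConfig()] fields, and optional `seed`.
#' @param outdir output directory.
#' @return (invisibly) the [simulateNailfold()] result plus paths.
#' @export
cmdSimulate <- function(config = list(), outdir = ".") {
  config <- .resolveSeeds(.loadRunConfig(config))
  cfg <- do.call(simConfig,
                 if (is.null(config$simulate)) list(seed = config$seed)
                 else config$simulate)
  sim <- simulateNailfold(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(raw = file.path(outdir, "dataset_raw.json"),
                curated = file.path(outdir, "dataset_curated.json"),
                truth = file.path(outdir, "ground_truth.json"))
  writeSpectraContainer(sim$raw, paths$raw)
  writeSpectraContainer(sim$curated, paths$curated)
  tr <- sim$truth
  .writeJSON(list(signal = .packMatrix(tr$signal),
                  background = .packMatrix(tr$background),
                  spikes = .packMatrix(tr$spikes),
                  noise = .packMatrix(tr$noise),
                  concentrations = tr$concentrations,
                  subject = tr$subject,
                  curatedIndex = tr$curatedIndex), paths$truth)
  invisible(c(sim, list(paths = paths)))
}
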