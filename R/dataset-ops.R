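# Partitioning into training/test/prediction sets and standard-deviation
# shift augmentation. All randomness is locally seeded: the caller's RNG
# state is left untouched and a given seed always yields the same result.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Split specification
#'
#' The partition protocol: a fixed-size prediction set is drawn first,
#' then the remainder is split into training and test sets by fraction
#' (default 80/20). Sizes follow `round()` (ties to even).
#'
#' @param nPrediction spectra held out as the prediction set (default 10).
#' @param trainFraction fraction of the remainder used for training,
#'   in (0, 1) (default 0.8).
#' @param seed integer seed for the random partition.
#' @return a validated `SplitSpec` list.
#' @export
splitSpec <- function(nPrediction = 10L, trainFraction = 0.8, seed = 1L) {
  if (nPrediction < 1L) stop("nPrediction must be >= 1", call. = FALSE)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)", call. = FALSE)
  structure(list(nPrediction = as.integer(nPrediction),
                 trainFraction = trainFraction, seed = as.integer(seed)),
            class = "SplitSpec")
}

#' Randomly partition a dataset into train/test/prediction sets
#'
#' Draws a uniformly random, seed-reproducible partition:
#' `nPrediction` spectra form the prediction set;
#' `round(trainFraction * (N - nPrediction))` of the rest are training,
#' the remainder test. The three sets are disjoint and exhaustive, and
#' every partition keeps its intensity columns paired with its targets
#' and ids.
#'
#' @param x a [RamanSpectra-class] object.
#' @param spec a [splitSpec()] object.
#' @return list with [RamanSpectra-class] elements `train`, `test`,
#'   `prediction`.
#' @export
splitDataset <- function(x, spec = splitSpec()) {
  if (!inherits(spec, "SplitSpec")) spec <- do.call(splitSpec, spec)
  n <- ncol(x)
  if (spec$nPrediction >= n)
    stop("nPrediction (", spec$nPrediction, ") must be < N (", n, ")",
         call. = FALSE)
  rest <- n - spec$nPrediction
  nTrain <- as.integer(round(spec$trainFraction * rest))
  nTest <- rest - nTrain
  if (nTrain < 1L || nTest < 1L)
    stop("split would leave an empty partition (train ", nTrain,
         ", test ", nTest, ")", call. = FALSE)
  perm <- .withSeed(spec$seed, sample.int(n))
  idxPred <- perm[seq_len(spec$nPrediction)]
  idxTrain <- perm[spec$nPrediction + seq_len(nTrain)]
  idxTest <- perm[spec$nPrediction + nTrain + seq_len(nTest)]
  list(train = x[, sort(idxTrain)],
       test = x[, sort(idxTest)],
       prediction = x[, sort(idxPred)])
}

#' Augmentation specification
#'
#' Standard-deviation-shift augmentation grows a dataset to
#' `factor` times its size by adding shifted copies of each spectrum.
#' In `"deterministic"` mode copy k of a spectrum x is
#' `x + c_k * sigma` with coefficients cycling `+s, -s, +2s, -2s, ...`
#' (`sigma` = per-wavenumber standard deviation across the input); in
#' `"stochastic"` mode each copy is `x + s * eps * sigma` with
#' `eps` i.i.d. standard normal per wavenumber.
#'
#' @param factor integer >= 1; output size = `factor` x input size.
#' @param shiftScale the dimensionless scale s > 0 (default 0.5).
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param seed integer seed (used by the stochastic mode).
#' @return a validated `AugmentSpec` list.
#' @export
augmentSpec <- function(factor = 4L, shiftScale = 0.5,
                        mode = c("deterministic", "stochastic"), seed = 1L) {
  mode <- match.arg(mode)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (shiftScale <= 0) stop("shiftScale must be > 0", call. = FALSE)
  structure(list(factor = as.integer(factor), shiftScale = shiftScale,
                 mode = mode, seed = as.integer(seed)),
            class = "AugmentSpec")
}

#' Standard-deviation-shift data augmentation
#'
#' See [augmentSpec()] for the scheme. The original spectra are returned
#' unchanged, first; copies inherit the target value of their source
#' spectrum and get ids suffixed `"_aug<k>"`. Intended for the training
#' partition only (augmenting before splitting leaks copies of test
#' spectra into training).
#'
#' @param x a [RamanSpectra-class] object with at least 2 spectra.
#' @param spec an [augmentSpec()] object.
#' @return augmented [RamanSpectra-class] with `factor * ncol(x)` spectra.
#' @export
augmentStdShift <- function(x, spec = augmentSpec()) {
  if (!inherits(spec, "AugmentSpec")) spec <- do.call(augmentSpec, spec)
  n <- ncol(x)
  if (n < 2L)
    stop("need at least 2 spectra to define the per-wavenumber ",
         "standard deviation", call. = FALSE)
  if (spec$factor == 1L) return(x)
  ints <- intensityMatrix(x)
  sigma <- apply(ints, 1, sd)
  s <- spec$shiftScale
  nCopies <- spec$factor - 1L
  copies <- .withSeed(spec$seed, lapply(seq_len(nCopies), function(k) {
    if (spec$mode == "deterministic") {
      ck <- ceiling(k / 2) * s * if (k %% 2L == 1L) 1 else -1
      ints + ck * sigma
    } else {
      eps <- matrix(rnorm(length(ints)), nrow(ints), ncol(ints))
      ints + s * eps * sigma
    }
  }))
  allInts <- do.call(cbind, c(list(ints), copies))
  ids <- c(spectraIDs(x),
           unlist(lapply(seq_len(nCopies), function(k)
             paste0(spectraIDs(x), "_aug", k))))
  RamanSpectra(wavenumbers(x), allInts,
               targets = rep(targets(x), spec$factor),
               ids = ids, unit = targetUnit(x))
}
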