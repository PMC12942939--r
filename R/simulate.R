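# Synthetic nailfold Raman dataset generator. Each emitted spectrum is
# the exact sum of four recorded components — pure Raman signal (fixed
# tissue bands plus a concentration-scaled glucose band at 1125 cm^-1),
# a broad fluorescence-like background with per-subject amplitude,
# cosmic-ray spikes, and additive Gaussian noise — so every
# preprocessing stage and model can be tested against ground truth.

.gauss <- function(w, center, sigma) exp(-(w - center)^2 / (2 * sigma^2))

#' Simulation configuration
#'
#' Defaults emulate a small in vivo glucose study: 15 subjects x 7
#' spectra on a 1024-point 800-1800 cm^-1 grid, glucose targets uniform
#' in 4.6-10.0 mmol/L (82.8-180 mg/dL at the 18.016 conversion), a
#' glucose band at 1125 cm^-1, strong fluorescence background, sparse
#' cosmic-ray spikes and additive noise; a curated subset of 75 spectra
#' (the lowest-noise realizations) stands in for manual quality
#' screening.
#'
#' @param nSubjects,spectraPerSubject cohort layout (raw N = product).
#' @param curatedSubset size of the curated subset (<= raw N).
#' @param gridPoints,gridLo,gridHi wavenumber grid (points, cm^-1 span).
#' @param glucoseLo,glucoseHi target range (mmol/L).
#' @param glucoseBandCenter,glucoseBandSigma glucose band position and
#'   width (cm^-1).
#' @param glucoseCoefficient band height per unit concentration
#'   (a.u. per mmol/L).
#' @param backgroundAmplitude baseline scale of the fluorescence
#'   background (a.u.); per-subject amplitudes vary +-20% around it.
#' @param fixedBands data.frame with columns `center`, `sigma`, `height`:
#'   concentration-independent tissue bands (generic Raman features).
#' @param spikeRate expected cosmic-ray spikes per spectrum (Poisson).
#' @param spikeAmplitude range (min, max) of spike heights (a.u.).
#' @param noiseSd additive Gaussian noise SD (a.u.).
#' @param unit declared target unit.
#' @param seed integer seed; generation is fully reproducible.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nSubjects = 15L, spectraPerSubject = 7L,
                      curatedSubset = 75L, gridPoints = 1024L,
                      gridLo = 800, gridHi = 1800,
                      glucoseLo = 4.6, glucoseHi = 10.0,
                      glucoseBandCenter = 1125, glucoseBandSigma = 8,
                      glucoseCoefficient = 1.0,
                      backgroundAmplitude = 200,
                      fixedBands = data.frame(
                        center = c(1003, 1305, 1450, 1655),
                        sigma = c(6, 10, 9, 11),
                        height = c(12, 8, 10, 14)),
                      spikeRate = 0.5, spikeAmplitude = c(50, 150),
                      noiseSd = 0.5, unit = "mmol/L", seed = 1L) {
  if (gridLo >= gridHi) stop("gridLo must be < gridHi", call. = FALSE)
  if (curatedSubset > nSubjects * spectraPerSubject)
    stop("curatedSubset exceeds the raw dataset size", call. = FALSE)
  if (glucoseLo >= glucoseHi)
    stop("glucoseLo must be < glucoseHi", call. = FALSE)
  if (glucoseCoefficient <= 0 || glucoseBandSigma <= 0 || gridPoints < 8)
    stop("scales must be positive", call. = FALSE)
  if (spikeRate < 0 || noiseSd < 0 || backgroundAmplitude < 0)
    stop("rates/amplitudes must be >= 0", call. = FALSE)
  structure(list(nSubjects = as.integer(nSubjects),
                 spectraPerSubject = as.integer(spectraPerSubject),
                 curatedSubset = as.integer(curatedSubset),
                 gridPoints = as.integer(gridPoints),
                 gridLo = gridLo, gridHi = gridHi,
                 glucoseLo = glucoseLo, glucoseHi = glucoseHi,
                 glucoseBandCenter = glucoseBandCenter,
                 glucoseBandSigma = glucoseBandSigma,
                 glucoseCoefficient = glucoseCoefficient,
                 backgroundAmplitude = backgroundAmplitude,
                 fixedBands = fixedBands,
                 spikeRate = spikeRate, spikeAmplitude = spikeAmplitude,
                 noiseSd = noiseSd, unit = unit, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a synthetic nailfold glucose dataset with ground truth
#'
#' Every spectrum is `signal + background + spikes + noise`, with each
#' component recorded in the returned ground truth (the sum reproduces
#' the emitted intensities exactly). Targets are per-spectrum glucose
#' concentrations drawn uniformly from the configured range; the
#' curated subset keeps the `curatedSubset` spectra with the smallest
#' injected-noise norm.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `raw` (all spectra as
#'   [RamanSpectra-class]), `curated` (the curated subset), and `truth`
#'   (list of `signal`, `background`, `spikes`, `noise` matrices, the
#'   `spikePositions` per spectrum, `concentrations`, `subject`, and
#'   `curatedIndex`).
#' @examples
#' sim <- simulateNailfold(simConfig(seed = 7))
#' ncol(sim$raw)      # 105
#' ncol(sim$curated)  # 75
#' @export
simulateNailfold <- function(config = simConfig()) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  cfg <- config
  w <- seq(cfg$gridLo, cfg$gridHi, length.out = cfg$gridPoints)
  m <- cfg$gridPoints
  n <- cfg$nSubjects * cfg$spectraPerSubject
  subject <- rep(seq_len(cfg$nSubjects), each = cfg$spectraPerSubject)
  fixedSig <- Reduce(`+`, lapply(seq_len(nrow(cfg$fixedBands)), function(i)
    cfg$fixedBands$height[i] *
      .gauss(w, cfg$fixedBands$center[i], cfg$fixedBands$sigma[i])))
  gBand <- .gauss(w, cfg$glucoseBandCenter, cfg$glucoseBandSigma)
  u <- (w - cfg$gridLo) / (cfg$gridHi - cfg$gridLo)
  bgShape <- 1 - 0.55 * u + 0.15 * u^2   # broad, smooth, decreasing
  out <- .withSeed(cfg$seed, {
    conc <- runif(n, cfg$glucoseLo, cfg$glucoseHi)
    subjAmp <- runif(cfg$nSubjects, 0.8, 1.2) * cfg$backgroundAmplitude
    signal <- fixedSig + outer(gBand, cfg$glucoseCoefficient * conc)
    background <- outer(bgShape, subjAmp[subject])
    spikes <- matrix(0, m, n)
    spikePositions <- vector("list", n)
    nSpk <- rpois(n, cfg$spikeRate)
    for (j in seq_len(n)) {
      if (nSpk[j] > 0) {
        pos <- sample.int(m, nSpk[j])
        spikes[pos, j] <- runif(nSpk[j], cfg$spikeAmplitude[1],
                                cfg$spikeAmplitude[2])
        spikePositions[[j]] <- pos
      } else spikePositions[[j]] <- integer(0)
    }
    noise <- matrix(rnorm(m * n, sd = cfg$noiseSd), m, n)
    list(conc = conc, signal = signal, background = background,
         spikes = spikes, spikePositions = spikePositions, noise = noise)
  })
  emitted <- out$signal + out$background + out$spikes + out$noise
  ids <- sprintf("S%02d_r%d", subject,
                 rep(seq_len(cfg$spectraPerSubject), cfg$nSubjects))
  raw <- RamanSpectra(w, emitted, targets = out$conc, ids = ids,
                      unit = cfg$unit)
  noiseNorm <- sqrt(colSums(out$noise^2))
  curatedIndex <- sort(order(noiseNorm)[seq_len(cfg$curatedSubset)])
  list(raw = raw,
       curated = raw[, curatedIndex],
       truth = list(signal = out$signal, background = out$background,
                    spikes = out$spikes, noise = out$noise,
                    spikePositions = out$spikePositions,
                    concentrations = out$conc, subject = subject,
                    curatedIndex = curatedIndex))
}

#' Noiseless (or noisy) linear mixture fixture for model tests
#'
#' Rows are random nonnegative combinations of the given constituent
#' profiles plus optional Gaussian noise; the response is the
#' coefficient of the first profile. Used to exercise PLSR/SVR recovery
#' on data with a known low-rank structure.
#'
#' @param n number of mixtures (rows).
#' @param profiles M x P matrix of constituent spectra (columns).
#' @param coefficients optional n x P nonnegative coefficient matrix;
#'   default uniform(0, 1) draws.
#' @param noiseSd additive noise SD (default 0).
#' @param seed integer seed.
#' @return list with `X` (n x M), `y` (= `coefficients[, 1]`) and
#'   `coefficients`.
#' @export
makeMixtureFixture <- function(n, profiles, coefficients = NULL,
                               noiseSd = 0, seed = 1L) {
  profiles <- as.matrix(profiles)
  p <- ncol(profiles)
  if (p < 1L) stop("need at least one profile", call. = FALSE)
  .withSeed(seed, {
    C <- if (is.null(coefficients))
      matrix(runif(n * p), n, p)
    else as.matrix(coefficients)
    if (nrow(C) != n || ncol(C) != p)
      stop("coefficients must be n x P", call. = FALSE)
    X <- C %*% t(profiles)
    if (noiseSd > 0) X <- X + matrix(rnorm(n * nrow(profiles),
                                           sd = noiseSd), n)
    list(X = X, y = C[, 1], coefficients = C)
  })
}
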