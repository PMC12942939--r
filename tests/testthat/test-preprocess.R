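test_that("crop keeps the closed interval and validates bounds", {
  ds <- RamanSpectra(1:5, matrix(1:10, 5, 2), targets = c(1, 2))
  expect_equal(wavenumbers(cropSpectra(ds, 2, 4)), c(2, 3, 4))
  expect_equal(targets(cropSpectra(ds, 2, 4)), c(1, 2))
  expect_equal(intensityMatrix(cropSpectra(ds, 1, 5)), intensityMatrix(ds))
  expect_error(cropSpectra(ds, 10, 11), "retains 0 points")
  expect_error(cropSpectra(ds, 4, 2), "lo must be < hi")
})

test_that("interpolation is exact on affine spectra and refuses to extrapolate", {
  w <- seq(800, 810, by = 1)
  ds <- RamanSpectra(w, cbind(2 * w + 1, -w + 5), targets = c(1, 2))
  same <- interpolateToGrid(ds, w)
  expect_equal(intensityMatrix(same), intensityMatrix(ds),
               ignore_attr = TRUE)
  grid <- seq(800.5, 809.5, by = 0.7)
  out <- interpolateToGrid(ds, grid)
  expect_equal(intensityMatrix(out)[, 1], 2 * grid + 1)
  # midpoint of a two-point linear interpolant
  ds2 <- RamanSpectra(c(800, 802, 804), matrix(c(0, 4, 0), 3, 1), targets = 1)
  expect_equal(intensityMatrix(interpolateToGrid(ds2, 801))[1, 1], 2,
               ignore_attr = TRUE)
  expect_error(interpolateToGrid(ds, c(799, 805)), "extrapolation")
})

test_that("median despiking removes single-channel spikes", {
  ds <- RamanSpectra(1:5, matrix(c(1, 1, 9, 1, 1), 5, 1), targets = 1)
  expect_equal(as.vector(intensityMatrix(despikeMedian(ds, 3))), rep(1, 5))
  const <- RamanSpectra(1:6, matrix(4, 6, 1), targets = 1)
  expect_equal(as.vector(intensityMatrix(despikeMedian(const, 3))), rep(4, 6))
  ramp <- RamanSpectra(1:4, matrix(1:4, 4, 1), targets = 1)
  expect_equal(as.vector(intensityMatrix(despikeMedian(ramp, 3)))[2:3], 2:3)
  expect_error(despikeMedian(ds, 4), "odd")
  expect_error(despikeMedian(ds, 7), "exceeds")
})

test_that("polynomial baseline removes model members and preserves peaks", {
  w <- seq(800, 1000, length.out = 120)
  bg <- 5 + 0.02 * w + 1e-4 * (w - 900)^2
  ds <- RamanSpectra(w, matrix(bg, ncol = 1), targets = 1)
  out <- baselinePolynomial(ds, degree = 2)
  expect_lt(max(abs(intensityMatrix(out))), 1e-8 * diff(range(bg)))

  expect_equal(baselinePolynomial(rep(3, 10), degree = 0), rep(0, 10),
               tolerance = 1e-12)

  peak <- 40 * exp(-(w - 920)^2 / (2 * 6^2))
  spiked <- baselinePolynomial(bg + peak, axis = w, degree = 2)
  apex <- max(spiked)
  expect_lt(abs(apex - 40) / 40, 0.05)
})

test_that("EMSC recovers the reference from exact model members", {
  w <- seq(800, 880, length.out = 40)
  m <- sin(seq(0, 3, length.out = 40)) + 2
  wNorm <- 2 * (w - min(w)) / diff(range(w)) - 1

  ds <- RamanSpectra(w, cbind(2 * m + 3, m), targets = c(1, 2))
  out <- intensityMatrix(baselineEmsc(ds, reference = m, degree = 0))
  expect_equal(out[, 1], m, tolerance = 1e-10)
  expect_equal(out[, 2], m, tolerance = 1e-10)

  ds2 <- RamanSpectra(w, cbind(1.5 * m + 2 + 0.5 * wNorm), targets = 1)
  out2 <- intensityMatrix(baselineEmsc(ds2, reference = m, degree = 1))
  expect_lt(max(abs(out2[, 1] - m)), 1e-8)

  # oracle: closed-form least squares on the same design matrix
  x <- 1.7 * m + 0.3 - 0.2 * wNorm + 0.1 * wNorm^2
  D <- cbind(m, 1, wNorm, wNorm^2)
  cf <- solve(crossprod(D), crossprod(D, x))
  corrected <- (x - D[, -1] %*% cf[-1]) / cf[1]
  ds3 <- RamanSpectra(w, cbind(x), targets = 1)
  expect_equal(intensityMatrix(baselineEmsc(ds3, m, degree = 2))[, 1],
               as.vector(corrected), tolerance = 1e-10)

  dsNeg <- RamanSpectra(w, cbind(-m), targets = 1)
  expect_error(baselineEmsc(dsNeg, reference = m, degree = 0), "degenerate")
})

test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  w <- seq(800, 900, length.out = 51)
  p <- 2 + 0.01 * w + 1e-4 * w^2 - 1e-6 * w^3
  ds <- RamanSpectra(w, matrix(p, ncol = 1), targets = 1)
  sm <- as.vector(intensityMatrix(smoothSavitzkyGolay(ds, 11, 3)))
  expect_lt(max(abs(sm - p)[6:46]), 1e-10 * max(abs(p)))

  set.seed(5)
  noise <- rnorm(51)
  dn <- RamanSpectra(w, matrix(noise, ncol = 1), targets = 1)
  smn <- as.vector(intensityMatrix(smoothSavitzkyGolay(dn, 11, 3)))
  expect_lt(var(smn), var(noise))

  ds3 <- RamanSpectra(1:3, matrix(c(0, 3, 0), 3, 1), targets = 1)
  expect_equal(intensityMatrix(smoothSavitzkyGolay(ds3, 3, 1))[2, 1], 1,
               ignore_attr = TRUE)

  expect_error(smoothSavitzkyGolay(ds, 10, 3), "odd")
  expect_error(smoothSavitzkyGolay(ds, 5, 5), "order")
})

test_that("area normalization sums to one and is idempotent", {
  ds <- RamanSpectra(1:3, matrix(c(1, 1, 2), 3, 1), targets = 1)
  out <- normalizeArea(ds)
  expect_equal(as.vector(intensityMatrix(out)), c(0.25, 0.25, 0.5))
  expect_equal(intensityMatrix(normalizeArea(out)), intensityMatrix(out))
  zero <- RamanSpectra(1:3, matrix(c(1, 0, -1), 3, 1), targets = 1,
                       ids = "z1")
  expect_error(normalizeArea(zero), "z1")
})

test_that("the chain applies stages in order and neutral config is identity", {
  ds <- toySpectra(m = 30, n = 4, seed = 2)
  neutral <- preprocessConfig(despikeWindow = NULL, baselineMethod = "none",
                              sgWindow = NULL, normalize = FALSE)
  res <- runPreprocessChain(ds, neutral)
  expect_equal(intensityMatrix(res$dataset), intensityMatrix(ds))
  expect_equal(nrow(res$report), 0L)

  res2 <- runPreprocessChain(ds, preprocessConfig(normalize = TRUE))
  expect_equal(res2$report$stage,
               c("despike", "baseline", "smooth", "normalize"))
  expect_equal(targets(res2$dataset), targets(ds))

  expect_error(preprocessConfig(sgWindow = 10), "odd")
  expect_error(preprocessConfig(cropLo = 5, cropHi = 2), "cropLo")
})

test_that("despike and smoothing are shift-equivariant and keep shape", {
  ds <- toySpectra(m = 40, n = 3, seed = 7)
  shifted <- RamanSpectra(wavenumbers(ds), intensityMatrix(ds) + 11,
                          targets = targets(ds))
  expect_equal(intensityMatrix(despikeMedian(shifted, 5)),
               intensityMatrix(despikeMedian(ds, 5)) + 11,
               ignore_attr = TRUE)
  expect_equal(intensityMatrix(smoothSavitzkyGolay(shifted, 7, 2)),
               intensityMatrix(smoothSavitzkyGolay(ds, 7, 2)) + 11,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("full chain recovers the pure signal on clean simulated data", {
  # the study grid (~1 cm^-1 spacing) so bands span several points and
  # the median filter removes spikes without flattening real peaks
  sim <- simulateNailfold(simConfig(nSubjects = 3, spectraPerSubject = 4,
                                    curatedSubset = 12, gridPoints = 1024,
                                    noiseSd = 0, spikeRate = 2, seed = 11))
  # baseline degree chosen to bracket the generator's smooth background;
  # higher degrees trade a little edge wiggle for flexibility on real data
  res <- runPreprocessChain(sim$raw, preprocessConfig(sgWindow = NULL,
                                                      polyDegree = 3))
  got <- intensityMatrix(res$dataset)
  truth <- sim$truth$signal
  relL2 <- sqrt(colSums((got - truth)^2)) / sqrt(colSums(truth^2))
  expect_lt(max(relL2), 0.05)
})
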