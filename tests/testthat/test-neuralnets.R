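test_that("transfer functions match their definitions", {
  expect_equal(tansig(0), 0)
  expect_gt(tansig(20), 1 - 1e-8)
  expect_equal(tansig(1), tanh(1))
  x <- seq(-3, 3, by = 0.5)
  expect_equal(tansig(x), tanh(x))
  expect_equal(relu(-3), 0)
  expect_equal(relu(5), 5)
  set.seed(1); v <- rnorm(50)
  expect_equal(relu(relu(v)), relu(v))
})

test_that("conv1dForward matches identity, delta and the brute-force oracle", {
  expect_equal(conv1dForward(c(4, 7, 2), 1), c(4, 7, 2))
  expect_equal(conv1dForward(c(1, 2, 3), c(0, 1, 0)), c(1, 2, 3))
  expect_equal(conv1dForward(c(1, 2, 3, 4), c(1, 0, -1)),
               bruteConv(c(1, 2, 3, 4), c(1, 0, -1)))
  set.seed(2)
  sig <- rnorm(17); ker <- rnorm(5)
  expect_equal(conv1dForward(sig, ker), bruteConv(sig, ker))
  expect_error(conv1dForward(sig, rnorm(4)), "odd")
})

test_that("MLP backprop gradients match finite differences", {
  set.seed(42)
  Xs <- matrix(rnorm(15), 5, 3)   # 5 features, 3 samples
  ys <- rnorm(3)
  W1 <- matrix(runif(10, -0.5, 0.5), 2, 5); b1 <- runif(2, -0.5, 0.5)
  W2 <- matrix(runif(2, -0.5, 0.5), 1, 2); b2 <- runif(1, -0.5, 0.5)
  g <- RamanQuant:::.mlpLossGrad(W1, b1, W2, b2, Xs, ys)
  loss <- function(W1., b1., W2., b2.)
    RamanQuant:::.mlpLossGrad(W1., b1., W2., b2., Xs, ys,
                              gradients = FALSE)$loss
  expect_lt(relErr(finiteDiff(function(v) loss(matrix(v, 2, 5), b1, W2, b2),
                              W1), g$dW1), 1e-6)
  expect_lt(relErr(finiteDiff(function(v) loss(W1, v, W2, b2), b1),
                   g$db1), 1e-6)
  expect_lt(relErr(finiteDiff(function(v) loss(W1, b1, matrix(v, 1, 2), b2),
                              W2), g$dW2), 1e-6)
  expect_lt(relErr(finiteDiff(function(v) loss(W1, b1, W2, v), b2),
                   g$db2), 1e-6)
})

test_that("MLP training stops early, is seeded, and scales updates with lr", {
  ds <- toySpectra(m = 10, n = 8, seed = 3)
  # an unreachable-low bar runs all epochs; a trivial bar stops at epoch 1
  big <- fitMlp(ds, mlpTrainSpec(epochs = 5, lossGoal = 1e6, seed = 2))
  expect_equal(length(big@trainLog), 1L)
  expect_lte(tail(big@trainLog, 1), 1e6)

  a <- fitMlp(ds, mlpTrainSpec(epochs = 10, seed = 4))
  b <- fitMlp(ds, mlpTrainSpec(epochs = 10, seed = 4))
  expect_identical(a@W1, b@W1)
  expect_identical(a@trainLog, b@trainLog)
  # early-stop contract: a model that stopped before the budget met the goal
  if (length(a@trainLog) < 10) expect_lte(tail(a@trainLog, 1), 1e-4)

  # first update is proportional to the learning rate
  m1 <- fitMlp(ds, mlpTrainSpec(epochs = 1, learningRate = 1e-3, seed = 5,
                                lossGoal = 1e-12))
  m2 <- fitMlp(ds, mlpTrainSpec(epochs = 1, learningRate = 1e-4, seed = 5,
                                lossGoal = 1e-12))
  init <- RamanQuant:::.withSeed(5L, {
    M <- 10; H <- 4
    list(W1 = matrix(runif(H * M, -0.5, 0.5), H, M))
  })
  u1 <- sqrt(sum((init$W1 - m1@W1)^2))
  u2 <- sqrt(sum((init$W1 - m2@W1)^2))
  expect_equal(u1 / u2, 10, tolerance = 1e-6)
})

test_that("MLP predictions invert the target scaling and check dimensions", {
  ds <- toySpectra(m = 10, n = 8, seed = 3)
  m <- fitMlp(ds, mlpTrainSpec(epochs = 3, seed = 1))
  p <- predict(m, ds)
  expect_equal(length(p), 8L)
  expect_true(all(is.finite(p)))
  expect_equal(length(predict(m, matrix(rnorm(10), 1, 10))), 1L)
  expect_error(predict(m, matrix(rnorm(9), 1, 9)), "features")
})

test_that("CNN architecture arithmetic and divisibility are enforced", {
  arch <- buildCnn(1024)
  expect_equal(length(arch@blocks), 4L)
  expect_equal(cnnFeatureLength(arch), 64L)
  expect_error(buildCnn(1000), "divisible")
  expect_error(buildCnn(1024, kernelWidth = 4), "odd")
})

test_that("CNN backprop gradients match finite differences for every group", {
  arch <- buildCnn(16, filters = c(2, 3), kernelWidth = 3, denseUnits = 4)
  params <- RamanQuant:::.cnnInitParams(arch, 1)
  set.seed(9)
  Xarr <- array(rnorm(16 * 4), c(16, 1, 4)); ys <- rnorm(4)
  lg <- RamanQuant:::.cnnLossGrad(params, Xarr, ys)
  for (nm in RamanQuant:::.cnnParamNames(params)) {
    th <- RamanQuant:::.cnnGetParam(params, nm)
    ga <- RamanQuant:::.cnnGetParam(lg$grads, nm)
    num <- finiteDiff(function(v) {
      v <- if (is.null(dim(th))) as.vector(v) else array(v, dim(th))
      RamanQuant:::.cnnLossGrad(RamanQuant:::.cnnSetParam(params, nm, v),
                                Xarr, ys)$loss
    }, th)
    expect_lt(relErr(num, as.array(ga)), 1e-6)
  }
})

test_that("max pooling is monotone and window-permutation invariant", {
  set.seed(4)
  A <- array(rnorm(12 * 2 * 3), c(12, 2, 3))
  p <- RamanQuant:::.poolForward(A, 2L)
  # increasing any input never decreases any pooled output
  A2 <- A; A2[5, 1, 2] <- A2[5, 1, 2] + 1
  p2 <- RamanQuant:::.poolForward(A2, 2L)
  expect_true(all(p2$out >= p$out))
  # swapping values within a pool window leaves the output unchanged
  A3 <- A; A3[c(5, 6), 1, 2] <- A[c(6, 5), 1, 2]
  expect_equal(RamanQuant:::.poolForward(A3, 2L)$out, p$out)
})

test_that("CNN can overfit a tiny noiseless linear problem", {
  set.seed(3)
  M <- 32; N <- 8
  X <- matrix(rnorm(N * M), N, M)
  y <- as.vector(X %*% rnorm(M) * 0.1)
  rs <- RamanSpectra(seq_len(M), t(X), targets = y)
  m <- fitCnn(rs, cnnTrainSpec(iterations = 2000, batchSize = 8, seed = 2),
              arch = buildCnn(M, filters = c(4, 8), kernelWidth = 3,
                              denseUnits = 16))
  expect_lt(mean((predict(m, rs) - y)^2), 1e-2 * var(y))
})

test_that("CNN training is seeded and honours the stop callback", {
  ds <- toySpectra(m = 16, n = 6, seed = 5)
  arch <- buildCnn(16, filters = c(2, 3), kernelWidth = 3, denseUnits = 4)
  a <- fitCnn(ds, cnnTrainSpec(iterations = 30, batchSize = 4, seed = 7),
              arch = arch)
  b <- fitCnn(ds, cnnTrainSpec(iterations = 30, batchSize = 4, seed = 7),
              arch = arch)
  expect_identical(a@trainLog, b@trainLog)
  expect_identical(predict(a, ds), predict(b, ds))

  stopped <- fitCnn(ds, cnnTrainSpec(iterations = 100, batchSize = 4,
                                     seed = 7),
                    arch = arch,
                    progressCallback = function(step, loss) step < 3)
  expect_equal(length(stopped@trainLog), 3L)

  expect_error(predict(buildCnn(16), ds), "untrained")
  expect_error(predict(a, toySpectra(m = 24, n = 2)), "points")
})

test_that("the first optimizer step shrinks in proportion to the learning rate", {
  ds <- toySpectra(m = 16, n = 6, seed = 5)
  arch <- buildCnn(16, filters = c(2, 3), kernelWidth = 3, denseUnits = 4)
  # MLP is plain gradient descent, so the ratio at step 1 is exact; for
  # the CNN Adam normalizes step length, so check the loss path is seeded
  # but lr-dependent
  a <- fitCnn(ds, cnnTrainSpec(iterations = 2, learningRate = 1e-3,
                               batchSize = 6, seed = 1), arch = arch)
  b <- fitCnn(ds, cnnTrainSpec(iterations = 2, learningRate = 1e-4,
                               batchSize = 6, seed = 1), arch = arch)
  expect_equal(a@trainLog[1], b@trainLog[1])     # same init, same batch
  expect_false(identical(a@trainLog[2], b@trainLog[2]))
})
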