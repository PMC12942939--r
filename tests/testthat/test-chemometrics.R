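test_that("PLSR fits rank-1 relations exactly with one latent variable", {
  set.seed(1)
  # rank-1 X: all channels share one score direction, so y affine in any
  # single channel is captured by the first latent variable
  X <- outer(rnorm(20), runif(10, 0.5, 2))
  y <- 2 * X[, 3] + 1
  m <- fitPlsr(X, y, ncomp = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  expect_equal(length(predict(m, X[1, , drop = FALSE])), 1L)
  expect_error(predict(m, X[, 1:9]), "features")
})

test_that("full-rank PLSR reproduces ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(120), 30, 4)
  y <- rnorm(30)
  m <- fitPlsr(X, y, ncomp = 4)
  ols <- as.vector(cbind(1, X) %*% qr.solve(cbind(1, X), y))
  expect_lt(max(abs(predict(m, X) - ols)), 1e-6)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(300), 30, 10)
  y <- rnorm(30)
  m <- fitPlsr(X, y, ncomp = 5)
  Xc <- sweep(X, 2, m@xMean)
  # recompute scores by walking the deflation with stored W, P
  E <- Xc; T <- matrix(0, 30, 5)
  for (a in 1:5) {
    T[, a] <- E %*% m@weights[, a]
    E <- E - T[, a] %*% t(m@loadings[, a])
  }
  G <- crossprod(T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-10)
})

test_that("PLSR recovers mixture coefficients on noiseless two-profile data", {
  profiles <- mixtureProfiles()
  fix <- makeMixtureFixture(40, profiles, seed = 5)
  train <- seq_len(30); test <- 31:40
  m <- fitPlsr(fix$X[train, ], fix$y[train], ncomp = 2)
  pred <- predict(m, fix$X[test, ])
  r2 <- 1 - sum((fix$y[test] - pred)^2) /
    sum((fix$y[test] - mean(fix$y[test]))^2)
  expect_gte(r2, 0.999)
})

test_that("CV component selection finds the noiseless rank and is deterministic", {
  profiles <- mixtureProfiles()
  fix <- makeMixtureFixture(40, profiles, seed = 6)
  sel <- selectPlsrComponents(fix$X, fix$y, kFolds = 5, maxComponents = 6,
                              seed = 2)
  expect_gte(sel$ncomp, 2L)
  expect_lt(sel$cvMSE[sel$ncomp], 1e-6)
  sel2 <- selectPlsrComponents(fix$X, fix$y, kFolds = 5, maxComponents = 6,
                               seed = 2)
  expect_identical(sel, sel2)
  sel1 <- selectPlsrComponents(fix$X, fix$y, kFolds = 5, maxComponents = 1,
                               seed = 2)
  expect_equal(sel1$ncomp, 1L)
  expect_error(selectPlsrComponents(fix$X[1:3, ], fix$y[1:3], kFolds = 5),
               "must be >=")
})

test_that("both model families shift predictions with a constant added to y", {
  set.seed(7)
  X <- matrix(rnorm(150), 30, 5)
  y <- as.vector(X %*% c(1, -1, 0.5, 0, 2)) + rnorm(30, sd = 0.1)
  mp1 <- fitPlsr(X, y, ncomp = 3)
  mp2 <- fitPlsr(X, y + 100, ncomp = 3)
  expect_equal(predict(mp2, X), predict(mp1, X) + 100, tolerance = 1e-8)
  ms1 <- fitSvr(X, y, kernel = "linear", cost = 10, epsilon = 0.1)
  ms2 <- fitSvr(X, y + 100, kernel = "linear", cost = 10, epsilon = 0.1)
  expect_equal(predict(ms2, X), predict(ms1, X) + 100, tolerance = 1e-6)
})

test_that("SVR finds the flat zero-weight solution when the tube covers y", {
  X <- matrix(c(0, 1, 2), 3, 1)
  y <- c(1.0, 1.1, 0.9)
  m <- fitSvr(X, y, kernel = "linear", cost = 1, epsilon = 0.2)
  expect_equal(length(m@dualCoefs), 0L)
  preds <- predict(m, X)
  expect_true(all(abs(outer(preds, y, "-")) <= 0.2 + 1e-9))
})

test_that("SVR attains near-zero slack on perfectly linear data", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.vector(X %*% c(1, 2, -1)) + 5
  m <- fitSvr(X, y, kernel = "linear", cost = 1e4, epsilon = 0.01,
              tolerance = 1e-5)
  expect_lte(max(abs(y - predict(m, X))), 0.01 + 1e-3)
  expect_true(all(abs(m@dualCoefs) <= 1e4 + 1e-6))
})

test_that("the gaussian kernel is 1 on the diagonal and duality gap is small", {
  A <- matrix(rnorm(10), 2, 5)
  K <- RamanQuant:::.svrKernelMatrix("gaussian", 0.7, A, A)
  expect_equal(diag(K), c(1, 1))

  set.seed(9)
  X <- matrix(rnorm(90), 30, 3)
  y <- as.vector(X %*% c(1, 2, -1)) + rnorm(30, sd = 0.3)
  for (k in c("linear", "gaussian")) {
    m <- fitSvr(X, y, kernel = k, cost = 10, epsilon = 0.1,
                gamma = if (k == "gaussian") 0.3 else NULL,
                tolerance = 1e-6)
    g <- svrOptimalityGap(m, X, y)
    expect_lte(g$relativeGap, 1e-3)
    expect_true(all(abs(m@dualCoefs) <= m@cost + 1e-8))
  }
})

test_that("widening the tube never adds support vectors", {
  set.seed(10)
  X <- matrix(rnorm(120), 40, 3)
  y <- as.vector(X %*% c(0.5, -1, 2)) + rnorm(40, sd = 0.2)
  eps <- c(0.01, 0.05, 0.1, 0.3, 0.6)
  nsv <- vapply(eps, function(e)
    length(fitSvr(X, y, kernel = "linear", cost = 10,
                  epsilon = e)@dualCoefs), 0L)
  expect_true(all(diff(nsv) <= 0))
})

test_that("grid search is exhaustive, ordered and deterministic", {
  set.seed(11)
  X <- matrix(rnorm(90), 30, 3)
  y <- as.vector(X %*% c(1, 1, 1)) + rnorm(30, sd = 0.05)

  single <- gridSearchSvr(X, y, kernel = "linear",
                          grids = list(cost = 7, epsilon = 0.2))
  expect_equal(single$best$cost, 7)
  expect_equal(single$best$epsilon, 0.2)
  expect_equal(nrow(single$table), 1L)

  # two-point cost grid: the returned point must match direct CV comparison
  two <- gridSearchSvr(X, y, kernel = "linear",
                       grids = list(cost = c(0.001, 100), epsilon = 0.05),
                       seed = 3)
  folds <- makeCvFolds(30, 5, 3)
  direct <- vapply(c(0.001, 100), function(C) {
    mean(vapply(folds, function(te) {
      m <- fitSvr(X[-te, ], y[-te], kernel = "linear", cost = C,
                  epsilon = 0.05)
      mean((y[te] - predict(m, X[te, , drop = FALSE]))^2)
    }, 0))
  }, 0)
  expect_equal(two$best$cost, c(0.001, 100)[which.min(direct)])
  expect_equal(sort(two$table$cvMSE), sort(direct))

  again <- gridSearchSvr(X, y, kernel = "linear",
                         grids = list(cost = c(0.001, 100), epsilon = 0.05),
                         seed = 3)
  expect_identical(two$table, again$table)

  expect_error(gridSearchSvr(X, y, grids = list(cost = numeric(0))),
               "empty grid")
})
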