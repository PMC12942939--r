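test_that("the hand-worked metric example and edge cases are exact", {
  r <- computeMetrics(c(1, 2, 3), c(1, 2, 4), "test")
  expect_equal(r@SSE, 1)
  expect_equal(r@MSE, 1 / 3)
  expect_equal(r@RMSE, sqrt(1 / 3))
  expect_equal(round(r@RMSE, 4), 0.5774)
  expect_equal(r@MAE, 1 / 3)
  expect_equal(r@R2, 0.5)
  expect_equal(r@COR, 0.98198, tolerance = 1e-5)

  perfect <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(perfect@SSE, perfect@MSE, perfect@RMSE, perfect@MAE),
               rep(0, 4))
  expect_equal(perfect@R2, 1)
  expect_equal(perfect@COR, 1)

  neg <- computeMetrics(c(0, 1), c(2, 0))
  expect_equal(neg@R2, -9)

  # constant predictions: zero variance in yhat -> COR undefined
  const <- computeMetrics(c(1, 2, 3), rep(2, 3))
  expect_equal(const@R2, 0)
  expect_true(is.na(const@COR))
  # constant observations: y variance zero -> both undefined
  consty <- computeMetrics(rep(2, 3), c(1, 2, 3))
  expect_true(is.na(consty@R2) && is.na(consty@COR))

  expect_error(computeMetrics(1:3, 1:2), "equal length")
  expect_error(computeMetrics(1, 1), "at least 2")
  expect_error(computeMetrics(c(1, Inf), c(1, 2)), "finite")
})

test_that("metrics agree with a naive-loop oracle on 1000 seeded pairs", {
  set.seed(123)
  for (rep in 1:1000) {
    n <- sample(2:12, 1)
    y <- rnorm(n); yhat <- rnorm(n)
    r <- computeMetrics(y, yhat)
    sse <- 0; sae <- 0
    for (i in seq_len(n)) {
      sse <- sse + (y[i] - yhat[i])^2
      sae <- sae + abs(y[i] - yhat[i])
    }
    ybar <- sum(y) / n; yhbar <- sum(yhat) / n
    ssy <- 0; ssyh <- 0; sxy <- 0
    for (i in seq_len(n)) {
      ssy <- ssy + (y[i] - ybar)^2
      ssyh <- ssyh + (yhat[i] - yhbar)^2
      sxy <- sxy + (y[i] - ybar) * (yhat[i] - yhbar)
    }
    expect_equal(r@SSE, sse, tolerance = 1e-12)
    expect_equal(r@MSE, sse / n, tolerance = 1e-12)
    expect_equal(r@RMSE, sqrt(sse / n), tolerance = 1e-12)
    expect_equal(r@MAE, sae / n, tolerance = 1e-12)
    expect_equal(r@R2, 1 - sse / ssy, tolerance = 1e-12)
    expect_equal(r@COR, sxy / sqrt(ssy * ssyh), tolerance = 1e-12)
  }
})

test_that("metric identities and invariances hold on random inputs", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    y <- rnorm(n, sd = runif(1, 0.5, 3)); yhat <- rnorm(n)
    r <- computeMetrics(y, yhat)
    expect_equal(r@RMSE^2, r@MSE, tolerance = 1e-12)
    expect_equal(r@n * r@MSE, r@SSE, tolerance = 1e-12)
    expect_lte(r@MAE, r@RMSE + 1e-12)
    # common affine rescaling leaves R2 unchanged
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    r2 <- computeMetrics(a * y + b, a * yhat + b)
    expect_equal(r2@R2, r@R2, tolerance = 1e-10)
    # separate positive affine rescaling leaves COR unchanged
    r3 <- computeMetrics(2 * y + 1, 0.3 * yhat - 4)
    expect_equal(r3@COR, r@COR, tolerance = 1e-10)
  }
})

test_that("evaluateModel wraps prediction and reports serialize fully", {
  set.seed(11)
  ds <- toySpectra(m = 12, n = 10, seed = 11)
  m <- fitPlsr(ds, ncomp = 2)
  rep <- evaluateModel(m, ds, "train")
  df <- as.data.frame(rep)
  expect_equal(names(df), c("partition", "n", "SSE", "MSE", "RMSE", "MAE",
                            "R2", "COR"))
  expect_equal(df$partition, "train")
  txt <- formatReport(rep)
  expect_equal(length(txt), 2L)
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$RMSE, rep@RMSE)

  # exact-fit model on its own training set scores R2 = 1
  y <- targets(ds)
  exact <- computeMetrics(y, y, "train")
  expect_equal(exact@R2, 1)
})

test_that("all four model families round-trip through archives unchanged", {
  ds <- toySpectra(m = 16, n = 10, seed = 21)
  X <- t(intensityMatrix(ds))
  td <- tempfile(); dir.create(td)
  models <- list(
    plsr = fitPlsr(ds, ncomp = 2),
    svr = fitSvr(ds, kernel = "gaussian", cost = 5, epsilon = 0.05,
                 gamma = 0.1),
    mlp = fitMlp(ds, mlpTrainSpec(epochs = 5, seed = 1)),
    cnn = fitCnn(ds, cnnTrainSpec(iterations = 10, batchSize = 5, seed = 1),
                 arch = buildCnn(16, filters = c(2, 3), kernelWidth = 3,
                                 denseUnits = 4)))
  for (nm in names(models)) {
    f <- file.path(td, paste0(nm, ".json"))
    saveModel(models[[nm]], f)
    back <- loadModel(f)
    expect_identical(predict(back, X), predict(models[[nm]], X),
                     info = nm)
  }
})

test_that("archives reject unknown families, bad versions and corruption", {
  ds <- toySpectra(m = 10, n = 6, seed = 2)
  m <- fitPlsr(ds, ncomp = 1)
  f <- tempfile(fileext = ".json")
  saveModel(m, f)

  a <- jsonlite::fromJSON(f, simplifyVector = TRUE, simplifyMatrix = FALSE)
  g <- tempfile(fileext = ".json")
  a$family <- "forest"
  writeLines(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA), g)
  expect_error(loadModel(g), "unknown model family")

  a$family <- "plsr"; a$version <- 99
  writeLines(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA), g)
  expect_error(loadModel(g), "incompatible")

  writeLines("{\"truncated\":", g)
  expect_error(loadModel(g), "corrupted|unreadable")

  writeLines("{\"format\": \"something-else\"}", g)
  expect_error(loadModel(g), "not a ramanquant-model")
})
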