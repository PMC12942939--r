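# One-hidden-layer perceptron regressor: tansig hidden layer, purelin
# (identity) output, trained by full-batch gradient descent on the MSE of
# min-max scaled targets, with early stopping on a loss goal. The classic
# companion scaling of tansig/purelin — per-feature min-max to [-1, 1] —
# is applied to inputs and targets and inverted at prediction time.

#' Hyperbolic-tangent sigmoid transfer function
#'
#' `tansig(x) = 2 / (1 + exp(-2x)) - 1`, identical to `tanh(x)`; range
#' (-1, 1).
#'
#' @param x numeric scalar, vector or array.
#' @return same shape as `x`.
#' @examples
#' tansig(0)      # 0
#' tansig(1)      # 0.761594...
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' MLP training specification
#'
#' Defaults match a small-sample spectral calibration setup: 4 hidden
#' neurons, 100 epochs, learning rate 0.001, loss goal 1e-4 (training
#' stops as soon as the epoch training MSE, in scaled units, reaches or
#' falls below the goal).
#'
#' @param hidden hidden-layer width H >= 1.
#' @param epochs maximum number of full-batch epochs.
#' @param learningRate gradient-descent step size.
#' @param lossGoal early-stopping target for the training MSE.
#' @param seed seed for the uniform \[-0.5, 0.5\] weight initialization.
#' @return a validated `MLPTrainSpec` list.
#' @export
mlpTrainSpec <- function(hidden = 4L, epochs = 100L, learningRate = 0.001,
                         lossGoal = 1e-4, seed = 1L) {
  if (hidden < 1L || epochs < 1L || learningRate <= 0 || lossGoal <= 0)
    stop("all MLP training parameters must be positive", call. = FALSE)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learningRate = learningRate, lossGoal = lossGoal,
                 seed = as.integer(seed)),
            class = "MLPTrainSpec")
}

.minmaxParams <- function(X) {
  # X: features x samples; degenerate (constant) features get span 1
  list(min = apply(X, 1, min), max = apply(X, 1, max))
}

.minmaxApply <- function(X, mn, mx) {
  span <- mx - mn; span[span == 0] <- 1
  2 * (X - mn) / span - 1
}

.minmaxInvert <- function(Xs, mn, mx) {
  span <- mx - mn; span[span == 0] <- 1
  (Xs + 1) / 2 * span + mn
}

# loss and analytic gradients of the scaled-MSE objective;
# Xs: M x B scaled inputs, ys: length-B scaled targets
.mlpLossGrad <- function(W1, b1, W2, b2, Xs, ys, gradients = TRUE) {
  B <- ncol(Xs)
  H1 <- tansig(W1 %*% Xs + b1)
  O <- as.vector(W2 %*% H1 + b2)
  err <- O - ys
  loss <- mean(err^2)
  if (!gradients) return(list(loss = loss))
  dO <- matrix(2 * err / B, nrow = 1)
  dW2 <- dO %*% t(H1)
  db2 <- sum(dO)
  dA1 <- (t(W2) %*% dO) * (1 - H1^2)
  list(loss = loss, dW1 = dA1 %*% t(Xs), db1 = rowSums(dA1),
       dW2 = dW2, db2 = db2)
}

#' Train a one-hidden-layer MLP regressor
#'
#' Full-batch gradient descent with backpropagation on the MSE of scaled
#' targets; weights initialized uniformly in \[-0.5, 0.5\] from the
#' spec's seed, so identical seeds give identical weight trajectories.
#' Training stops early at the first epoch whose training MSE is at or
#' below `lossGoal`, otherwise after `epochs` epochs.
#'
#' @param train a [RamanSpectra-class] object with known targets, or an
#'   N x M matrix (then supply `y`).
#' @param spec an [mlpTrainSpec()].
#' @param validation optional [RamanSpectra-class] whose MSE is logged
#'   per epoch alongside the training loss (no effect on stopping).
#' @param y response vector when `train` is a matrix.
#' @return a fitted [MLPModel-class]; `@trainLog` holds the per-epoch
#'   training MSE (scaled units).
#' @export
fitMlp <- function(train, spec = mlpTrainSpec(), validation = NULL, y = NULL) {
  if (!inherits(spec, "MLPTrainSpec")) spec <- do.call(mlpTrainSpec, spec)
  if (is(train, "RamanSpectra")) {
    X <- intensityMatrix(train)  # M x N
    y <- targets(train)
  } else {
    X <- t(as.matrix(train))
    if (is.null(y)) stop("y required when train is a matrix", call. = FALSE)
  }
  if (ncol(X) < 1L || anyNA(y))
    stop("training set must be nonempty with known targets", call. = FALSE)
  mm <- .minmaxParams(X)
  Xs <- .minmaxApply(X, mm$min, mm$max)
  yMin <- min(y); yMax <- max(y)
  ys <- as.vector(.minmaxApply(matrix(y, nrow = 1), yMin, yMax))
  M <- nrow(Xs); H <- spec$hidden
  init <- .withSeed(spec$seed, list(
    W1 = matrix(runif(H * M, -0.5, 0.5), H, M),
    b1 = runif(H, -0.5, 0.5),
    W2 = matrix(runif(H, -0.5, 0.5), 1, H),
    b2 = runif(1, -0.5, 0.5)))
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  valX <- if (!is.null(validation)) {
    .minmaxApply(intensityMatrix(validation), mm$min, mm$max)
  }
  lr <- spec$learningRate
  trainLog <- numeric(0); valLog <- numeric(0)
  for (epoch in seq_len(spec$epochs)) {
    g <- .mlpLossGrad(W1, b1, W2, b2, Xs, ys)
    W1 <- W1 - lr * g$dW1; b1 <- b1 - lr * g$db1
    W2 <- W2 - lr * g$dW2; b2 <- b2 - lr * g$db2
    loss <- .mlpLossGrad(W1, b1, W2, b2, Xs, ys, gradients = FALSE)$loss
    if (!is.finite(loss))
      stop("MLP training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    trainLog <- c(trainLog, loss)
    if (!is.null(validation)) {
      vo <- as.vector(W2 %*% tansig(W1 %*% valX + b1) + b2)
      vy <- .minmaxInvert(vo, yMin, yMax)
      valLog <- c(valLog, mean((targets(validation) - vy)^2))
    }
    if (loss <= spec$lossGoal) break
  }
  new("MLPModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      xMin = mm$min, xMax = mm$max, yMin = yMin, yMax = yMax,
      trainLog = trainLog,
      spec = c(unclass(spec), list(valLog = valLog)),
      preprocess = list(),
      unit = if (is(train, "RamanSpectra")) targetUnit(train)
             else NA_character_)
}

#' @describeIn fitMlp predict targets for new spectra.
#' @param object a fitted `MLPModel`.
#' @param newdata N x M matrix or [RamanSpectra-class].
#' @param ... ignored.
#' @export
setMethod("predict", "MLPModel", function(object, newdata, ...) {
  X <- if (is(newdata, "RamanSpectra")) intensityMatrix(newdata)
       else t(as.matrix(newdata))
  if (nrow(X) != length(object@xMin))
    stop("newdata has ", nrow(X), " features; model expects ",
         length(object@xMin), call. = FALSE)
  Xs <- .minmaxApply(X, object@xMin, object@xMax)
  o <- as.vector(object@W2 %*% tansig(object@W1 %*% Xs + object@b1) +
                   object@b2)
  as.vector(.minmaxInvert(o, object@yMin, object@yMax))
})

#' @describeIn MLPModel compact display.
#' @param object an `MLPModel`.
#' @export
setMethod("show", "MLPModel", function(object) {
  cat("MLPModel: ", length(object@xMin), "-", nrow(object@W1),
      "-1 (tansig/purelin), ", length(object@trainLog),
      " epoch(s) trained, final MSE ",
      format(tail(object@trainLog, 1), digits = 4), " (scaled)\n", sep = "")
  invisible(NULL)
})
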