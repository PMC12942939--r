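# One-dimensional convolutional network regressor: four (by default)
# blocks of same-padded cross-correlation + ReLU + max pooling, a ReLU
# dense layer on the flattened feature maps, and a single linear output
# neuron. Trained by mini-batch adaptive-moment gradient descent on the
# MSE of min-max scaled targets. Convolutions are evaluated as matrix
# products on an unrolled (im2col) view; backpropagation mirrors the
# same index bookkeeping and is checked against finite differences in
# the test suite.

#' Rectified linear unit
#'
#' `max(0, x)` elementwise; idempotent.
#'
#' @param x numeric scalar, vector or array.
#' @return same shape as `x`.
#' @export
relu <- function(x) pmax(x, 0)

#' Same-padded 1D cross-correlation of a signal with a kernel
#'
#' Zero padding keeps the output length equal to the input length; the
#' kernel width must be odd so the window is centred.
#'
#' @param signal numeric vector.
#' @param kernel odd-length numeric vector.
#' @return numeric vector, `length(signal)`.
#' @examples
#' conv1dForward(c(1, 2, 3), c(0, 1, 0))  # c(1, 2, 3)
#' @export
conv1dForward <- function(signal, kernel) {
  k <- length(kernel)
  if (k %% 2L == 0L)
    stop("kernel width must be odd (got ", k, ")", call. = FALSE)
  n <- length(signal)
  p <- (k - 1L) %/% 2L
  padded <- c(rep(0, p), signal, rep(0, p))
  out <- numeric(n)
  for (o in seq_len(k)) out <- out + kernel[o] * padded[o:(o + n - 1L)]
  out
}

#' CNN training specification
#'
#' @param iterations number of optimizer steps (default 1000).
#' @param learningRate Adam step size (default 0.001).
#' @param batchSize mini-batch size (default 16).
#' @param seed seed for initialization and batch shuffling.
#' @return a validated `CNNTrainSpec` list.
#' @export
cnnTrainSpec <- function(iterations = 1000L, learningRate = 0.001,
                         batchSize = 16L, seed = 1L) {
  if (iterations < 1L || learningRate <= 0 || batchSize < 1L)
    stop("all CNN training parameters must be positive", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize), seed = as.integer(seed)),
            class = "CNNTrainSpec")
}

#' Build an (untrained) 1D CNN architecture
#'
#' The default architecture is four blocks of
#' `conv(width 5, same padding, ReLU) -> maxpool(2, stride 2)` with
#' 8/16/32/64 filters, a 32-unit ReLU dense layer on the flattened
#' features, and a single linear output neuron. The input length must be
#' divisible by the product of the pool widths (16 by default).
#'
#' @param inputLength number of wavenumber points M.
#' @param filters integer vector, one filter count per block.
#' @param kernelWidth odd convolution kernel width (shared by blocks).
#' @param poolWidth max-pooling width and stride (shared by blocks).
#' @param denseUnits width of the dense layer.
#' @return an untrained [CNNModel-class]; see [cnnFeatureLength()].
#' @export
buildCnn <- function(inputLength, filters = c(8L, 16L, 32L, 64L),
                     kernelWidth = 5L, poolWidth = 2L, denseUnits = 32L) {
  if (kernelWidth %% 2L == 0L)
    stop("kernelWidth must be odd", call. = FALSE)
  if (any(filters < 1L) || denseUnits < 1L || poolWidth < 2L)
    stop("filters, denseUnits and poolWidth must be positive", call. = FALSE)
  shrink <- poolWidth^length(filters)
  if (inputLength %% shrink != 0L)
    stop("input length ", inputLength, " is not divisible by ", shrink,
         " (product of pool widths); interpolate the spectra to a ",
         "compatible grid first (see interpolateToGrid)", call. = FALSE)
  blocks <- lapply(seq_along(filters), function(i)
    list(filters = as.integer(filters[i]), kernel = as.integer(kernelWidth),
         pool = as.integer(poolWidth)))
  new("CNNModel", inputLength = as.integer(inputLength), blocks = blocks,
      Wd = matrix(0, 0, 0), bd = numeric(0), Wo = matrix(0, 0, 0),
      bo = numeric(0), xMin = numeric(0), xMax = numeric(0),
      yMin = NA_real_, yMax = NA_real_, trainLog = numeric(0),
      spec = list(filters = as.integer(filters),
                  kernelWidth = as.integer(kernelWidth),
                  poolWidth = as.integer(poolWidth),
                  denseUnits = as.integer(denseUnits),
                  featureLength = as.integer(inputLength %/% shrink)),
      preprocess = list(), unit = NA_character_)
}

#' Flattened feature length per filter of a CNN architecture
#'
#' @param model a [CNNModel-class].
#' @return integer: input length divided by the product of pool widths.
#' @export
cnnFeatureLength <- function(model) model@spec$featureLength

# ---- forward / backward primitives on arrays of dim (L, C, B) ----

.convForward <- function(A, W, b) {
  dA <- dim(A); L <- dA[1]; Ci <- dA[2]; B <- dA[3]
  k <- dim(W)[1]; Co <- dim(W)[3]; p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  Ap <- array(0, c(Lp, Ci, B))
  Ap[(p + 1L):(p + L), , ] <- A
  base <- rep(0:(k - 1L), Ci) + rep((0:(Ci - 1L)) * Lp, each = k)
  idx0 <- outer(base, seq_len(L), "+")                       # (k*Ci) x L
  idxAll <- outer(as.vector(idx0), (seq_len(B) - 1L) * (Lp * Ci), "+")
  colX <- matrix(Ap[idxAll], k * Ci, L * B)
  outMat <- crossprod(colX, matrix(W, k * Ci, Co))           # (L*B) x Co
  outMat <- outMat + rep(b, each = L * B)
  out <- aperm(array(outMat, c(L, B, Co)), c(1, 3, 2))       # (L, Co, B)
  list(out = out, colX = colX, dims = c(L = L, Ci = Ci, B = B, k = k,
                                        Co = Co, p = p, Lp = Lp))
}

.convBackward <- function(dOut, cache, W) {
  d <- cache$dims
  dOutMat <- matrix(aperm(dOut, c(1, 3, 2)), d["L"] * d["B"], d["Co"])
  dW <- array(cache$colX %*% dOutMat, dim = dim(W))
  db <- colSums(dOutMat)
  dAp <- array(0, c(d["Lp"], d["Ci"], d["B"]))
  for (o in seq_len(d["k"])) {
    Wo <- matrix(W[o, , ], d["Ci"], d["Co"])
    tmp <- aperm(array(dOutMat %*% t(Wo), c(d["L"], d["B"], d["Ci"])),
                 c(1, 3, 2))
    rows <- o:(o + d["L"] - 1L)
    dAp[rows, , ] <- dAp[rows, , , drop = FALSE] + tmp
  }
  dA <- dAp[(d["p"] + 1L):(d["p"] + d["L"]), , , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

.poolForward <- function(A, w) {
  L <- dim(A)[1]
  best <- A[seq(1L, L, by = w), , , drop = FALSE]
  arg <- array(1L, dim(best))
  if (w > 1L) for (o in 2:w) {
    cand <- A[seq(o, L, by = w), , , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(out = best, arg = arg, inLength = L, w = w)
}

.poolBackward <- function(dOut, cache) {
  dA <- array(0, c(cache$inLength, dim(dOut)[2], dim(dOut)[3]))
  for (o in seq_len(cache$w)) {
    mask <- cache$arg == o
    sub <- dA[seq(o, cache$inLength, by = cache$w), , , drop = FALSE]
    sub[mask] <- dOut[mask]
    dA[seq(o, cache$inLength, by = cache$w), , ] <- sub
  }
  dA
}

.cnnForward <- function(params, Xarr) {
  caches <- vector("list", length(params$blocks))
  A <- Xarr
  for (i in seq_along(params$blocks)) {
    bl <- params$blocks[[i]]
    cv <- .convForward(A, bl$W, bl$b)
    Z <- cv$out
    R <- relu(Z)
    pl <- .poolForward(R, bl$pool)
    caches[[i]] <- list(conv = cv, reluMask = Z > 0, pool = pl)
    A <- pl$out
  }
  B <- dim(A)[3]
  Fmat <- matrix(A, prod(dim(A)[1:2]), B)
  Hd <- relu(params$Wd %*% Fmat + params$bd)
  O <- as.vector(params$Wo %*% Hd + params$bo)
  list(out = O, caches = caches, Fmat = Fmat, Hd = Hd,
       flatDim = dim(A)[1:2])
}

.cnnLossGrad <- function(params, Xarr, ys) {
  fw <- .cnnForward(params, Xarr)
  B <- length(ys)
  err <- fw$out - ys
  loss <- mean(err^2)
  dO <- matrix(2 * err / B, nrow = 1)
  dWo <- dO %*% t(fw$Hd)
  dbo <- sum(dO)
  dHd <- (t(params$Wo) %*% dO) * (fw$Hd > 0)
  dWd <- dHd %*% t(fw$Fmat)
  dbd <- rowSums(dHd)
  dF <- t(params$Wd) %*% dHd
  dA <- array(dF, c(fw$flatDim, B))
  gBlocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    ch <- fw$caches[[i]]
    dR <- .poolBackward(dA, ch$pool)
    dZ <- dR * ch$reluMask
    bk <- .convBackward(dZ, ch$conv, params$blocks[[i]]$W)
    gBlocks[[i]] <- list(W = bk$dW, b = bk$db)
    dA <- bk$dA
  }
  list(loss = loss,
       grads = list(blocks = gBlocks, Wd = dWd, bd = dbd, Wo = dWo,
                    bo = dbo))
}

.cnnInitParams <- function(arch, seed) {
  .withSeed(seed, {
    Ci <- 1L
    blocks <- lapply(arch@blocks, function(bl) {
      k <- bl$kernel; Co <- bl$filters
      lim <- sqrt(6 / (k * Ci))
      W <- array(runif(k * Ci * Co, -lim, lim), c(k, Ci, Co))
      Ci <<- Co
      list(W = W, b = numeric(Co), pool = bl$pool)
    })
    Fdim <- arch@spec$featureLength * tail(arch@spec$filters, 1)
    H <- arch@spec$denseUnits
    list(blocks = blocks,
         Wd = matrix(runif(H * Fdim, -sqrt(6 / Fdim), sqrt(6 / Fdim)),
                     H, Fdim),
         bd = numeric(H),
         Wo = matrix(runif(H, -sqrt(6 / H), sqrt(6 / H)), 1, H),
         bo = 0)
  })
}

# flat list view of the parameter tree, for the Adam updates
.cnnParamNames <- function(params) {
  c(unlist(lapply(seq_along(params$blocks), function(i)
    paste0("blocks.", i, ".", c("W", "b")))), "Wd", "bd", "Wo", "bo")
}

.cnnGetParam <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "blocks") params$blocks[[as.integer(parts[2])]][[parts[3]]]
  else params[[name]]
}

.cnnSetParam <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "blocks")
    params$blocks[[as.integer(parts[2])]][[parts[3]]] <- value
  else params[[name]] <- value
  params
}

#' Train a 1D CNN regressor
#'
#' Minimizes the MSE of min-max scaled targets by mini-batch
#' adaptive-moment (Adam) gradient descent for `iterations` optimizer
#' steps; batches are drawn from a seeded shuffle that reshuffles each
#' epoch. A progress callback, if given, is invoked per step with
#' `(step, loss)`; returning `FALSE` stops training after that step
#' (the batch loss log then has exactly that many entries).
#'
#' @param train a [RamanSpectra-class] with known targets, or an N x M
#'   matrix with `y`.
#' @param spec a [cnnTrainSpec()].
#' @param arch an untrained architecture from [buildCnn()]; default:
#'   `buildCnn(M)` for the training grid.
#' @param progressCallback optional `function(step, loss)`.
#' @param y response vector when `train` is a matrix.
#' @return a fitted [CNNModel-class]; `@trainLog` holds the per-step
#'   batch loss (scaled units), and `@spec$stepsPerEpoch` records the
#'   step/epoch equivalence.
#' @export
fitCnn <- function(train, spec = cnnTrainSpec(), arch = NULL,
                   progressCallback = NULL, y = NULL) {
  if (!inherits(spec, "CNNTrainSpec")) spec <- do.call(cnnTrainSpec, spec)
  if (is(train, "RamanSpectra")) {
    X <- intensityMatrix(train)
    y <- targets(train)
  } else {
    X <- t(as.matrix(train))
    if (is.null(y)) stop("y required when train is a matrix", call. = FALSE)
  }
  if (ncol(X) < 1L || anyNA(y))
    stop("training set must be nonempty with known targets", call. = FALSE)
  M <- nrow(X); N <- ncol(X)
  if (is.null(arch)) arch <- buildCnn(M)
  if (arch@inputLength != M)
    stop("architecture expects ", arch@inputLength, " points, data has ", M,
         call. = FALSE)
  mm <- .minmaxParams(X)
  Xs <- .minmaxApply(X, mm$min, mm$max)
  yMin <- min(y); yMax <- max(y)
  ys <- as.vector(.minmaxApply(matrix(y, nrow = 1), yMin, yMax))
  params <- .cnnInitParams(arch, spec$seed)
  pnames <- .cnnParamNames(params)
  mState <- setNames(lapply(pnames, function(nm)
    .cnnGetParam(params, nm) * 0), pnames)
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  lr <- spec$learningRate
  bs <- min(spec$batchSize, N)
  trainLog <- numeric(0)
  # derive a deterministic epoch-shuffle stream from the spec seed
  order <- integer(0); epochCounter <- 0L
  nextBatch <- function() {
    if (length(order) < bs) {
      epochCounter <<- epochCounter + 1L
      order <<- c(order, .withSeed(spec$seed + epochCounter, sample.int(N)))
    }
    b <- order[seq_len(bs)]
    order <<- order[-seq_len(bs)]
    b
  }
  for (step in seq_len(spec$iterations)) {
    idx <- nextBatch()
    Xarr <- array(Xs[, idx], c(M, 1L, length(idx)))
    lg <- .cnnLossGrad(params, Xarr, ys[idx])
    if (!is.finite(lg$loss))
      stop("CNN training diverged (non-finite loss) at step ", step,
           call. = FALSE)
    for (nm in pnames) {
      g <- .cnnGetParam(lg$grads, nm)
      mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * g
      vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * g^2
      mHat <- mState[[nm]] / (1 - beta1^step)
      vHat <- vState[[nm]] / (1 - beta2^step)
      params <- .cnnSetParam(params, nm,
                             .cnnGetParam(params, nm) -
                               lr * mHat / (sqrt(vHat) + adamEps))
    }
    trainLog <- c(trainLog, lg$loss)
    if (!is.null(progressCallback) &&
        identical(progressCallback(step, lg$loss), FALSE)) break
  }
  model <- arch
  model@blocks <- params$blocks
  model@Wd <- params$Wd; model@bd <- params$bd
  model@Wo <- params$Wo; model@bo <- params$bo
  model@xMin <- mm$min; model@xMax <- mm$max
  model@yMin <- yMin; model@yMax <- yMax
  model@trainLog <- trainLog
  model@spec <- c(arch@spec, unclass(spec),
                  list(stepsPerEpoch = ceiling(N / bs),
                       epochsRun = length(trainLog) / ceiling(N / bs)))
  model@unit <- if (is(train, "RamanSpectra")) targetUnit(train)
                else NA_character_
  model
}

#' @describeIn fitCnn predict targets for new spectra.
#' @param object a fitted `CNNModel`.
#' @param newdata N x M matrix or [RamanSpectra-class].
#' @param ... ignored.
#' @export
setMethod("predict", "CNNModel", function(object, newdata, ...) {
  X <- if (is(newdata, "RamanSpectra")) intensityMatrix(newdata)
       else t(as.matrix(newdata))
  if (length(object@xMin) == 0L)
    stop("model is untrained; call fitCnn() first", call. = FALSE)
  if (nrow(X) != object@inputLength)
    stop("newdata has ", nrow(X), " points; model expects ",
         object@inputLength, call. = FALSE)
  Xs <- .minmaxApply(X, object@xMin, object@xMax)
  params <- list(blocks = object@blocks, Wd = object@Wd, bd = object@bd,
                 Wo = object@Wo, bo = object@bo)
  o <- .cnnForward(params, array(Xs, c(nrow(X), 1L, ncol(X))))$out
  as.vector(.minmaxInvert(o, object@yMin, object@yMax))
})

#' @describeIn CNNModel compact display.
#' @param object a `CNNModel`.
#' @export
setMethod("show", "CNNModel", function(object) {
  cat("CNNModel: ", object@inputLength, " points, ",
      length(object@blocks), " conv+pool blocks (",
      paste(object@spec$filters, collapse = "/"), " filters), ",
      if (length(object@trainLog)) paste0(length(object@trainLog),
                                          " step(s) trained")
      else "untrained", "\n", sep = "")
  invisible(NULL)
})
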