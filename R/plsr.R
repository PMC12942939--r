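# NIPALS partial least squares regression (single response) and
# cross-validated latent-variable selection. The model is Y = X.B + E on
# centered data; latent scores are extracted to maximize covariance with
# the response and are mutually orthogonal.

#' Seeded cross-validation folds
#'
#' Shuffles `1:n` with the given seed and cuts the shuffled order into
#' `k` contiguous blocks. The same fold engine is shared by PLSR
#' latent-variable selection and the SVR grid search.
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` integer index vectors.
#' @export
makeCvFolds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("n (", n, ") must be >= k (", k, ")", call. = FALSE)
  perm <- .withSeed(seed, sample.int(n))
  split(perm, cut(seq_len(n), breaks = k, labels = FALSE))
}

# core NIPALS on centered data; returns weights W, loadings P, y-loadings q
.nipals <- function(Xc, yc, ncomp) {
  m <- ncol(Xc)
  W <- matrix(0, m, ncomp); P <- matrix(0, m, ncomp); q <- numeric(ncomp)
  E <- Xc; f <- yc
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2))
  a <- 0L
  for (j in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12 * max(scale0, 1)) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < .Machine$double.eps) break
    p <- crossprod(E, t) / tt
    qj <- sum(f * t) / tt
    E <- E - t %*% t(p)
    f <- f - qj * t
    W[, j] <- w; P[, j] <- p; q[j] <- qj
    a <- j
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], ncomp = a)
}

.plsrCoef <- function(fit, a = fit$ncomp) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  as.vector(W %*% solve(crossprod(P, W), q))
}

#' Fit a PLSR model by NIPALS
#'
#' @param X numeric N x M matrix, one spectrum per row (or a
#'   [RamanSpectra-class] object).
#' @param y numeric response vector of length N (taken from the targets
#'   when `X` is a `RamanSpectra`).
#' @param ncomp number of latent variables, `1 <= ncomp <= min(N-1, M)`.
#' @return a fitted [PLSRModel-class]. If score deflation collapses before
#'   `ncomp` components are extracted, the effective count is reduced with
#'   a warning.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 3] * 2 + 1
#' m <- fitPlsr(X, y, ncomp = 1)
#' max(abs(predict(m, X) - y)) < 1e-8
#' @export
fitPlsr <- function(X, y = NULL, ncomp) {
  if (is(X, "RamanSpectra")) {
    if (is.null(y)) y <- targets(X)
    X <- .modelMatrix(X)
  }
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("y must have one value per row of X", call. = FALSE)
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite", call. = FALSE)
  if (ncomp < 1L || ncomp > min(n - 1L, m))
    stop("ncomp must be in [1, min(N-1, M)] = [1, ", min(n - 1L, m), "]",
         call. = FALSE)
  xMean <- colMeans(X); yMean <- mean(y)
  fit <- .nipals(sweep(X, 2, xMean), y - yMean, ncomp)
  if (fit$ncomp < ncomp)
    warning("deflation collapsed after ", fit$ncomp, " of ", ncomp,
            " components; effective ncomp reduced", call. = FALSE)
  if (fit$ncomp == 0L) stop("X has no covariance with y", call. = FALSE)
  new("PLSRModel", ncomp = fit$ncomp, xMean = xMean, yMean = yMean,
      coefficients = .plsrCoef(fit), weights = fit$W, loadings = fit$P,
      yloadings = fit$q, preprocess = list(), unit = NA_character_)
}

#' @describeIn fitPlsr predict targets for new spectra (rows of `newdata`,
#'   or a `RamanSpectra`).
#' @param object a fitted `PLSRModel`.
#' @param newdata N x M matrix or [RamanSpectra-class].
#' @param ... ignored.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  X <- if (is(newdata, "RamanSpectra")) .modelMatrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != length(object@xMean))
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object@xMean), call. = FALSE)
  as.vector(sweep(X, 2, object@xMean) %*% object@coefficients) + object@yMean
})

#' Choose the PLSR latent-variable count by cross-validation
#'
#' Computes the mean cross-validated MSE for every component count from 1
#' to `maxComponents` and returns the count with the smallest average MSE,
#' breaking ties toward fewer components.
#'
#' @param X N x M matrix or [RamanSpectra-class].
#' @param y response vector (defaults to the targets of `X`).
#' @param kFolds number of CV folds (default 5).
#' @param maxComponents largest count tried; default
#'   `min(20, N - 1 - ceiling(N / kFolds), M)` so every training fold can
#'   support it.
#' @param seed fold seed.
#' @return list with `ncomp` (the selected count) and `cvMSE` (the mean CV
#'   MSE curve, one value per component count).
#' @export
selectPlsrComponents <- function(X, y = NULL, kFolds = 5L,
                                 maxComponents = NULL, seed = 1L) {
  if (is(X, "RamanSpectra")) {
    if (is.null(y)) y <- targets(X)
    X <- .modelMatrix(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < kFolds) stop("N (", n, ") must be >= kFolds", call. = FALSE)
  folds <- makeCvFolds(n, kFolds, seed)
  maxFold <- max(lengths(folds))
  cap <- min(20L, n - 1L - maxFold, ncol(X))
  if (is.null(maxComponents)) maxComponents <- cap
  maxComponents <- as.integer(min(maxComponents, n - 1L - maxFold, ncol(X)))
  if (maxComponents < 1L) stop("too few samples for CV", call. = FALSE)
  se <- matrix(NA_real_, length(folds), maxComponents)
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    Xtr <- X[-test, , drop = FALSE]; ytr <- y[-test]
    xMean <- colMeans(Xtr); yMean <- mean(ytr)
    fit <- .nipals(sweep(Xtr, 2, xMean), ytr - yMean, maxComponents)
    Xte <- sweep(X[test, , drop = FALSE], 2, xMean)
    for (a in seq_len(maxComponents)) {
      aa <- min(a, fit$ncomp)
      pred <- as.vector(Xte %*% .plsrCoef(fit, aa)) + yMean
      se[fi, a] <- mean((y[test] - pred)^2)
    }
  }
  cvMSE <- colMeans(se)
  list(ncomp = which.min(cvMSE), cvMSE = cvMSE)
}

#' @describeIn PLSRModel compact display.
#' @param object a `PLSRModel`.
#' @export
setMethod("show", "PLSRModel", function(object) {
  cat("PLSRModel (NIPALS): ", object@ncomp, " latent variable(s), ",
      length(object@xMean), " spectral channels\n", sep = "")
  invisible(NULL)
})
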