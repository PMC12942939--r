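# epsilon-support-vector regression behind the package's model surface.
# The quadratic program is solved by libsvm (via e1071); features are
# standardized internally, predictions use the package's own dual
# expansion (which also covers the zero-support-vector flat solution),
# and KKT / duality-gap diagnostics are computed independently from the
# returned dual coefficients.

.svrKernelMatrix <- function(kernel, gamma, A, B) {
  if (kernel == "linear") return(A %*% t(B))
  # gaussian: exp(-gamma * ||a - b||^2)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

.svrStandardize <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Fit an epsilon-support-vector regression model
#'
#' Minimizes `0.5 ||w||^2 + C sum(xi + xi*)` subject to the
#' epsilon-insensitive constraints; residuals smaller than `epsilon`
#' cost nothing, so points strictly inside the tube carry zero dual
#' coefficient (sparse solution). Features are standardized to zero
#' mean / unit variance internally (recorded in the model); `epsilon`
#' stays in target units.
#'
#' @param X N x M matrix (spectra as rows) or [RamanSpectra-class].
#' @param y response vector (defaults to targets of `X`).
#' @param kernel `"linear"` or `"gaussian"`.
#' @param cost regularization parameter C > 0.
#' @param epsilon tube half-width (target units), >= 0.
#' @param gamma Gaussian kernel width (> 0); default `1 / M`. Ignored by
#'   the linear kernel.
#' @param tolerance solver stopping tolerance (default 1e-3); tighten for
#'   stricter KKT satisfaction at large `cost`.
#' @return a fitted [SVRModel-class].
#' @export
fitSvr <- function(X, y = NULL, kernel = c("linear", "gaussian"),
                   cost = 1, epsilon = 0.1, gamma = NULL,
                   tolerance = 1e-3) {
  kernel <- match.arg(kernel)
  if (is(X, "RamanSpectra")) {
    if (is.null(y)) y <- targets(X)
    X <- .modelMatrix(X)
  }
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y must match rows of X", call. = FALSE)
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  if (kernel == "gaussian" && gamma <= 0)
    stop("gamma must be > 0 for the gaussian kernel", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, sd); scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- .svrStandardize(X, center, scale)
  fit <- e1071::svm(Xs, y, type = "eps-regression",
                    kernel = if (kernel == "linear") "linear" else "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    tolerance = tolerance, scale = FALSE, fitted = FALSE)
  nsv <- fit$tot.nSV
  sv <- if (nsv > 0) as.matrix(fit$SV) else matrix(0, 0, ncol(X))
  coefs <- if (nsv > 0) as.vector(fit$coefs) else numeric(0)
  idx <- if (nsv > 0) as.integer(fit$index) else integer(0)
  new("SVRModel", kernel = kernel, cost = cost, epsilon = epsilon,
      gamma = if (kernel == "gaussian") gamma else NA_real_,
      supportVectors = sv, dualCoefs = coefs, bias = -fit$rho,
      svIndex = idx, xCenter = center, xScale = scale,
      preprocess = list(), unit = NA_character_)
}

#' @describeIn fitSvr predict targets for new spectra.
#' @param object a fitted `SVRModel`.
#' @param newdata N x M matrix or [RamanSpectra-class].
#' @param ... ignored.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, ...) {
  X <- if (is(newdata, "RamanSpectra")) .modelMatrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != length(object@xCenter))
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object@xCenter), call. = FALSE)
  Xs <- .svrStandardize(X, object@xCenter, object@xScale)
  if (nrow(object@supportVectors) == 0L)
    return(rep(object@bias, nrow(Xs)))
  K <- .svrKernelMatrix(object@kernel,
                        if (is.na(object@gamma)) 0 else object@gamma,
                        Xs, object@supportVectors)
  as.vector(K %*% object@dualCoefs) + object@bias
})

#' Optimality diagnostics for a fitted SVR model
#'
#' Recomputes the primal objective (from the dual expansion of `||w||^2`
#' plus the epsilon-insensitive slack at `cost`) and the dual objective
#' from the stored dual coefficients, returning both and their gap. At
#' the libsvm solution the relative gap is small (the convergence
#' contract), and `|a_i| <= C` for every support vector.
#'
#' @param model a fitted [SVRModel-class].
#' @param X,y the training spectra and targets the model was fitted on.
#' @return list with `primal`, `dual`, `gap` and `relativeGap`.
#' @export
svrOptimalityGap <- function(model, X, y) {
  if (is(X, "RamanSpectra")) {
    if (is.null(y)) y <- targets(X)
    X <- .modelMatrix(X)
  }
  a <- model@dualCoefs
  g <- if (is.na(model@gamma)) 0 else model@gamma
  wNorm2 <- if (length(a))
    as.numeric(t(a) %*% .svrKernelMatrix(model@kernel, g,
                                         model@supportVectors,
                                         model@supportVectors) %*% a)
  else 0
  resid <- abs(y - predict(model, X))
  slack <- pmax(0, resid - model@epsilon)
  primal <- 0.5 * wNorm2 + model@cost * sum(slack)
  ySV <- y[model@svIndex]
  dual <- -0.5 * wNorm2 - model@epsilon * sum(abs(a)) + sum(a * ySV)
  gap <- primal - dual
  list(primal = primal, dual = dual, gap = gap,
       relativeGap = gap / (1 + abs(primal)))
}

#' Grid search for SVR hyperparameters
#'
#' Exhaustive k-fold cross-validation over the Cartesian product of the
#' given parameter values; returns the combination with the smallest mean
#' CV MSE along with the full CV table.
#'
#' @param X N x M matrix or [RamanSpectra-class].
#' @param y response vector (defaults to targets of `X`).
#' @param kernel `"linear"` or `"gaussian"`.
#' @param grids named list of parameter value vectors; recognized names
#'   `cost`, `epsilon` and (gaussian only) `gamma`. Defaults:
#'   `cost` 0.01-1000 by decades, `epsilon` \{0.01, 0.1, 0.5\}, `gamma`
#'   1e-4-1 by decades.
#' @param kFolds number of folds (default 5).
#' @param seed fold seed.
#' @return list with `best` (named parameter list), `bestMSE`, and
#'   `table` (data.frame of every combination and its mean CV MSE).
#' @export
gridSearchSvr <- function(X, y = NULL, kernel = c("linear", "gaussian"),
                          grids = list(), kFolds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (is(X, "RamanSpectra")) {
    if (is.null(y)) y <- targets(X)
    X <- .modelMatrix(X)
  }
  X <- as.matrix(X)
  defaults <- list(cost = 10^(-2:3), epsilon = c(0.01, 0.1, 0.5),
                   gamma = 10^(-4:0))
  for (nm in names(grids)) {
    if (!nm %in% names(defaults))
      stop("unknown grid dimension '", nm, "'", call. = FALSE)
    if (length(grids[[nm]]) == 0L)
      stop("empty grid for '", nm, "'", call. = FALSE)
  }
  grids <- utils::modifyList(defaults, grids)
  if (kernel == "linear") grids$gamma <- NA_real_
  tab <- expand.grid(cost = grids$cost, epsilon = grids$epsilon,
                     gamma = grids$gamma, KEEP.OUT.ATTRS = FALSE)
  folds <- makeCvFolds(nrow(X), kFolds, seed)
  tab$cvMSE <- vapply(seq_len(nrow(tab)), function(i) {
    mse <- vapply(folds, function(test) {
      m <- fitSvr(X[-test, , drop = FALSE], y[-test], kernel = kernel,
                  cost = tab$cost[i], epsilon = tab$epsilon[i],
                  gamma = if (kernel == "gaussian") tab$gamma[i] else NULL)
      mean((y[test] - predict(m, X[test, , drop = FALSE]))^2)
    }, 0)
    mean(mse)
  }, 0)
  best <- tab[which.min(tab$cvMSE), ]
  list(best = list(cost = best$cost, epsilon = best$epsilon,
                   gamma = if (kernel == "gaussian") best$gamma else NULL),
       bestMSE = best$cvMSE, table = tab)
}

#' @describeIn SVRModel compact display.
#' @param object an `SVRModel`.
#' @export
setMethod("show", "SVRModel", function(object) {
  cat("SVRModel (", object@kernel, " kernel): C = ", object@cost,
      ", epsilon = ", object@epsilon,
      if (object@kernel == "gaussian") paste0(", gamma = ", object@gamma),
      "; ", nrow(object@supportVectors), " support vectors\n", sep = "")
  invisible(NULL)
})
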