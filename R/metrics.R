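# The six regression evaluation statistics: SSE, MSE (divisor n), RMSE,
# MAE, coefficient of determination R^2 (may be negative), and the
# Pearson correlation COR (undefined -> NA when either variance term is
# zero).

#' Compute the six regression evaluation statistics
#'
#' `SSE = sum((y - yhat)^2)`, `MSE = SSE / n`, `RMSE = sqrt(MSE)`,
#' `MAE = mean(|y - yhat|)`,
#' `R2 = 1 - SSE / sum((y - mean(y))^2)` (negative when the predictor is
#' worse than the mean; `NA` when y is constant), and `COR` the Pearson
#' correlation between y and yhat (`NA` when either variance term is
#' zero).
#'
#' @param y observed targets, length n >= 2, finite.
#' @param yhat predicted targets, same length.
#' @param partition label: `"train"`, `"test"` or `"prediction"`.
#' @return an [EvaluationReport-class].
#' @examples
#' computeMetrics(c(1, 2, 3), c(1, 2, 4), "test")
#' @export
computeMetrics <- function(y, yhat, partition = "test") {
  if (length(y) != length(yhat))
    stop("y (", length(y), ") and yhat (", length(yhat),
         ") must have equal length", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    stop("y and yhat must be finite", call. = FALSE)
  partition <- match.arg(partition, c("train", "test", "prediction"))
  r <- y - yhat
  sse <- sum(r^2)
  mse <- sse / n
  ssy <- sum((y - mean(y))^2)
  ssyh <- sum((yhat - mean(yhat))^2)
  r2 <- if (ssy == 0) NA_real_ else 1 - sse / ssy
  cor <- if (ssy == 0 || ssyh == 0) NA_real_
         else sum((y - mean(y)) * (yhat - mean(yhat))) / sqrt(ssy * ssyh)
  new("EvaluationReport", n = n, SSE = sse, MSE = mse, RMSE = sqrt(mse),
      MAE = mean(abs(r)), R2 = r2, COR = cor, partition = partition)
}

#' Evaluate a fitted model on a dataset
#'
#' @param model any fitted model with a `predict` method (PLSR, SVR, MLP
#'   or CNN).
#' @param data a [RamanSpectra-class] with known targets.
#' @param partition label for the report.
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(model, data, partition = "test") {
  y <- targets(data)
  if (anyNA(y)) stop("dataset has missing targets", call. = FALSE)
  computeMetrics(y, predict(model, data), partition)
}

#' @describeIn EvaluationReport one-row data.frame with all six
#'   statistics.
#' @param x an `EvaluationReport`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "EvaluationReport", function(x, ...) {
  data.frame(partition = x@partition, n = x@n, SSE = x@SSE, MSE = x@MSE,
             RMSE = x@RMSE, MAE = x@MAE, R2 = x@R2, COR = x@COR,
             stringsAsFactors = FALSE)
})

#' @describeIn EvaluationReport aligned-table display.
#' @param object an `EvaluationReport`.
#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat(formatReport(object), sep = "\n")
  invisible(NULL)
})

#' Format an evaluation report as an aligned plain-text table
#'
#' @param ... one or more [EvaluationReport-class] objects.
#' @return character vector of table lines.
#' @export
formatReport <- function(...) {
  reports <- list(...)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  rows <- cbind(partition = format(c("partition", df$partition)),
                n = format(c("n", df$n)),
                vapply(c("SSE", "MSE", "RMSE", "MAE", "R2", "COR"),
                       function(s) format(c(s, sprintf("%.4f", df[[s]]))),
                       character(nrow(df) + 1L)))
  apply(rows, 1, paste, collapse = "  ")
}

.reportToList <- function(report) {
  list(partition = report@partition, n = report@n, SSE = report@SSE,
       MSE = report@MSE, RMSE = report@RMSE, MAE = report@MAE,
       R2 = report@R2, COR = report@COR)
}

#' Write an evaluation report to disk
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @param format `"json"` (full precision, deterministic) or `"text"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") .writeJSON(.reportToList(report), path)
  else writeLines(formatReport(report), path)
  invisible(path)
}
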