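# Prediction-ability statistics and the surrogate comparison report.

check_pair <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' differ in length")
  if (length(observed) < 1) stop("empty input")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values")
  list(y = observed, yhat = predicted)
}

#' Absolute average deviation (AAD, percent)
#'
#' `100/n * sum(|yhat_i - y_i| / y_i)`: the mean relative absolute
#' error, in percent of each observation.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return AAD in percent.
#' @export
aad <- function(observed, predicted) {
  v <- check_pair(observed, predicted)
  zero <- which(v$y == 0)
  if (length(zero))
    stop("observed value is zero at index ", zero[1],
         "; AAD is undefined there")
  100 * mean(abs(v$yhat - v$y) / abs(v$y))
}

#' Root mean square error
#'
#' `sqrt(sum((yhat - y)^2) / n)`, in the units of the response.
#'
#' @inheritParams aad
#' @export
rmse <- function(observed, predicted) {
  v <- check_pair(observed, predicted)
  sqrt(mean((v$yhat - v$y)^2))
}

#' Standard error of prediction (SEP, percent)
#'
#' RMSE expressed as a percentage of the observed mean:
#' `100 * rmse / mean(y)`.
#'
#' @inheritParams aad
#' @export
sep <- function(observed, predicted) {
  v <- check_pair(observed, predicted)
  if (mean(v$y) == 0) stop("mean of observed values is zero; SEP undefined")
  100 * rmse(observed, predicted) / mean(v$y)
}

#' Coefficient of determination of predictions
#'
#' `1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`. Unlike a fitted
#' model's R2 this can be negative for predictions worse than the
#' observed mean.
#'
#' @inheritParams aad
#' @export
r2_score <- function(observed, predicted) {
  v <- check_pair(observed, predicted)
  sst <- sum((v$y - mean(v$y))^2)
  if (sst <= 0) stop("observed values have zero variance; R2 undefined")
  1 - sum((v$yhat - v$y)^2) / sst
}

#' Compare the prediction ability of two surrogates
#'
#' Computes AAD, SEP, RMSE and R2 for each response under each of two
#' prediction sets (typically the response-surface and neural
#' surrogates) and issues a per-response, per-metric verdict on which
#' predicts better (lower AAD/SEP/RMSE, higher R2).
#'
#' @param observed Data frame of observed responses.
#' @param rsm_pred,ann_pred Data frames of predictions with the same
#'   response columns.
#' @param responses Response columns to compare; defaults to the columns
#'   of `observed` present in both prediction sets.
#' @return An object of class `model_comparison`: `metrics` (long data
#'   frame: model, response, aad, sep, rmse, r2, n) and `verdicts`
#'   (response x metric winner, `"rsm"`, `"ann"` or `"tie"`).
#' @export
compare_models <- function(observed, rsm_pred, ann_pred,
                           responses = NULL) {
  observed <- as.data.frame(observed)
  rsm_pred <- as.data.frame(rsm_pred)
  ann_pred <- as.data.frame(ann_pred)
  if (is.null(responses))
    responses <- intersect(names(observed),
                           intersect(names(rsm_pred), names(ann_pred)))
  if (!length(responses)) stop("no common response columns")
  for (r in responses)
    for (d in list(observed, rsm_pred, ann_pred))
      if (is.null(d[[r]])) stop("missing response column '", r, "'")

  one <- function(model, pred) {
    do.call(rbind, lapply(responses, function(r) data.frame(
      model = model, response = r,
      aad = aad(observed[[r]], pred[[r]]),
      sep = sep(observed[[r]], pred[[r]]),
      rmse = rmse(observed[[r]], pred[[r]]),
      r2 = r2_score(observed[[r]], pred[[r]]),
      n = length(observed[[r]]), stringsAsFactors = FALSE)))
  }
  metrics <- rbind(one("rsm", rsm_pred), one("ann", ann_pred))

  verdict <- function(r, metric, lower_is_better) {
    a <- metrics[metrics$model == "rsm" & metrics$response == r, metric]
    b <- metrics[metrics$model == "ann" & metrics$response == r, metric]
    if (a == b) "tie"
    else if (xor(a < b, !lower_is_better)) "rsm"
    else "ann"
  }
  verdicts <- do.call(rbind, lapply(responses, function(r) data.frame(
    response = r,
    aad = verdict(r, "aad", TRUE), sep = verdict(r, "sep", TRUE),
    rmse = verdict(r, "rmse", TRUE), r2 = verdict(r, "r2", FALSE),
    stringsAsFactors = FALSE)))

  structure(list(metrics = metrics, verdicts = verdicts),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Prediction-ability comparison\n")
  m <- x$metrics
  m[c("aad", "sep", "rmse")] <- lapply(m[c("aad", "sep", "rmse")], round, 3)
  m$r2 <- round(m$r2, 4)
  print(m, row.names = FALSE)
  cat("Better model by metric:\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}
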