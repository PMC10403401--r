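# Evaluation metrics -----------------------------------------------------------

check_pair <- function(true, pred, min_len = 1L) {
  if (length(true) != length(pred)) stop("`true` and `pred` length mismatch")
  if (length(true) < min_len) stop("need at least ", min_len, " pairs")
  if (any(!is.finite(true)) || any(!is.finite(pred))) stop("non-finite value")
}

#' Mean absolute percentage error
#'
#' `(100 / m) * sum(|y - yhat| / |y|)`. Undefined when any true value is 0.
#'
#' @param true,pred numeric vectors of equal length (>= 1).
#' @return MAPE in percent.
#' @export
mape <- function(true, pred) {
  check_pair(true, pred)
  if (any(true == 0)) {
    bad <- which(true == 0)
    lab <- if (!is.null(names(true))) names(true)[bad] else bad
    stop("MAPE undefined: true value is 0 at ", paste(lab, collapse = ", "))
  }
  mean(abs(true - pred) / abs(true)) * 100
}

#' Maximum absolute error
#'
#' @inheritParams mape
#' @return `max(|y - yhat|)`, in the units of the inputs.
#' @export
max_abs_error <- function(true, pred) {
  check_pair(true, pred)
  max(abs(true - pred))
}

#' Coefficient of determination
#'
#' `1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`; the denominator is the
#' total sum of squares about the mean of the true values.
#'
#' @param true,pred numeric vectors of equal length (>= 2); `true` must have
#'   positive variance.
#' @export
r_squared <- function(true, pred) {
  check_pair(true, pred, min_len = 2L)
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("R^2 undefined: true values have zero variance")
  1 - sum((pred - true)^2) / ss_tot
}

#' Training loss of the direct route (scalar targets)
#'
#' Mean squared error over the evaluation set: one output per experiment.
#'
#' @param true,pred numeric vectors of equal length.
#' @export
mse_direct <- function(true, pred) {
  check_pair(true, pred)
  mean((true - pred)^2)
}

#' Training loss of the indirect route (voltage-matrix targets)
#'
#' Mean squared error normalised by experiments times time points:
#' `sum((Y - Yhat)^2) / (n * n2)`.
#'
#' @param true,pred numeric matrices of identical dimension (experiments x
#'   time points).
#' @export
mse_indirect <- function(true, pred) {
  true <- as.matrix(true); pred <- as.matrix(pred)
  if (!identical(dim(true), dim(pred))) stop("matrix dimension mismatch")
  if (any(!is.finite(true)) || any(!is.finite(pred))) stop("non-finite value")
  sum((true - pred)^2) / (nrow(true) * ncol(true))
}

#' Regression metrics bundle
#'
#' @inheritParams mape
#' @return object of class `metrics_report` with `mape` (%),
#'   `max_abs_error`, `r2`, `n`.
#' @export
metrics_report <- function(true, pred) {
  structure(
    list(mape = mape(true, pred),
         max_abs_error = max_abs_error(true, pred),
         r2 = r_squared(true, pred),
         n = length(true)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d: MAPE %.2f%%, MAX %.2f, R2 %.3f\n",
              x$n, x$mape, x$max_abs_error, x$r2))
  invisible(x)
}

#' Pollution classification scores
#'
#' A sample is labelled polluted iff its BOD is at or above `threshold`
#' (applied identically to true and predicted values; use a mg/L threshold
#' on concentrations from [mass_to_concentration()], or a mg threshold on
#' masses — the scale must match the inputs). Sensitivity is the fraction of
#' truly polluted samples identified; specificity the fraction of truly
#' unpolluted samples identified; accuracy the overall fraction correct.
#' A score with an empty reference class is reported as `NA`, not 0.
#'
#' @param true_bod,pred_bod numeric vectors on the same scale.
#' @param threshold pollution threshold (> 0), same scale as the inputs.
#' @return object of class `classification_report` with `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, and the confusion counts.
#' @export
classify_and_score <- function(true_bod, pred_bod, threshold) {
  check_pair(true_bod, pred_bod)
  if (threshold <= 0) stop("`threshold` must be > 0")
  true_pos <- true_bod >= threshold
  pred_pos <- pred_bod >= threshold
  p <- sum(true_pos); n_neg <- sum(!true_pos)
  sens <- if (p > 0) sum(pred_pos & true_pos) / p else NA_real_
  spec <- if (n_neg > 0) sum(!pred_pos & !true_pos) / n_neg else NA_real_
  acc <- mean(pred_pos == true_pos)
  structure(
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         threshold = threshold, n_polluted = p, n_unpolluted = n_neg),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> threshold %.3g: sens %.3f, spec %.3f, acc %.3f (%d/%d pol/unpol)\n",
    x$threshold, x$sensitivity, x$specificity, x$accuracy,
    x$n_polluted, x$n_unpolluted))
  invisible(x)
}
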