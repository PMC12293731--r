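#' Confusion table for aneurysm screening
#'
#' 2x2 counts with aneurysm as the positive class.
#'
#' @param tp,fp,fn,tn non-negative integer counts; at least one positive.
#' @return Object of class `confusion_table`.
#' @examples
#' confusion_table(tp = 15, fp = 2, fn = 2, tn = 14)
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty confusion table", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2,
              dimnames = list(c("actual normal", "actual aneurysm"),
                              c("pred normal", "pred aneurysm")))
  print(m)
  invisible(x)
}

#' Interval Dice coefficient
#'
#' Dice = 2TP / (2TP + FP + FN) computed on the inclusive slice-index sets of
#' a predicted and an annotated aneurysm interval, i.e. overlap quality along
#' the axial axis. An absent prediction (`NULL`) scores 0.
#'
#' @param pred a [boundary_interval()] or `NULL` (no detection).
#' @param truth a [boundary_interval()].
#' @return Dice in `[0, 1]`.
#' @examples
#' interval_dice(boundary_interval(10, 20), boundary_interval(15, 25)) # 12/22
#' @export
interval_dice <- function(pred, truth) {
  stopifnot(inherits(truth, "boundary_interval"))
  if (is.null(pred)) return(0)
  stopifnot(inherits(pred, "boundary_interval"))
  tp <- max(0L, min(pred$end, truth$end) - max(pred$start, truth$start) + 1L)
  fp <- interval_length(pred) - tp
  fn <- interval_length(truth) - tp
  2 * tp / (2 * tp + fp + fn)
}

#' Dice coefficient of two binary masks
#'
#' 2D companion of [interval_dice()] for mask-vs-mask comparisons.
#'
#' @param a,b binary matrices of identical dimension.
#' @return Dice in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  tp <- sum(a != 0 & b != 0)
  denom <- 2 * tp + sum(a != 0 & b == 0) + sum(a == 0 & b != 0)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS`, the proportion of variance in the true values
#' explained by the predictions.
#'
#' @param y_true,y_pred numeric vectors of equal length `>= 2`; `y_true`
#'   must not be constant.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r2 <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  if (length(y_true) < 2L) stop("need n >= 2 for R^2", call. = FALSE)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("R^2 undefined for constant y_true", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / tss
}

#' Mean absolute error
#' @param y_true,y_pred numeric vectors of equal length.
#' @return mean of `|y_true - y_pred|`.
#' @export
mae <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

#' Mean squared error
#' @param y_true,y_pred numeric vectors of equal length.
#' @return mean of `(y_true - y_pred)^2`.
#' @export
mse <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  mean((y_true - y_pred)^2)
}

#' Binary cross-entropy
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, with predictions clipped to `[eps, 1 - eps]`.
#'
#' @param y_true binary vector (0/1).
#' @param y_pred probabilities in `[0, 1]`.
#' @param eps clipping constant, default `1e-7`.
#' @return non-negative BCE value.
#' @export
bce <- function(y_true, y_pred, eps = 1e-7) {
  check_paired(y_true, y_pred)
  if (any(y_true != 0 & y_true != 1)) {
    stop("y_true must be binary for BCE", call. = FALSE)
  }
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' @noRd
check_paired <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must be non-empty and of equal length",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Classification metrics from a confusion table
#'
#' Accuracy, precision, recall, specificity and F1 with aneurysm as the
#' positive class. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param cm a [confusion_table()].
#' @return named list with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`.
#' @examples
#' classification_metrics(confusion_table(tp = 15, fp = 2, fn = 2, tn = 14))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_table"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(cm$tp, cm$tp + cm$fp)
  recall <- div(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(accuracy = div(cm$tp + cm$tn, total),
       precision = precision,
       recall = recall,
       specificity = div(cm$tn, cm$tn + cm$fp),
       f1 = f1)
}

#' Boundary-detection performance report
#'
#' Summarizes a detector's predictions against annotated boundaries in the
#' standard comparison layout: R-squared, MAE and MSE for the start and end
#' slice indices, mean interval Dice, and (when signals are supplied)
#' R-squared between surrogate volumes computed over the predicted and the
#' true interval. Absent predictions score 0 in Dice and are excluded from
#' the start/end regressions and the volume regression; `n_absent` reports
#' how many were excluded.
#'
#' @param predictions list of [boundary_interval()] or `NULL` entries.
#' @param truths list of [boundary_interval()], aligned with `predictions`.
#' @param signals optional list of [area_signal()], aligned; enables the
#'   volume R-squared column.
#' @param model label for the row, e.g. `"expert"` or `"lstm"`.
#' @return one-row `data.frame` with columns `model`, `r2_start`, `r2_end`,
#'   `mae_start`, `mae_end`, `mse_start`, `mse_end`, `dice`, `r2_volume`,
#'   `n`, `n_absent`.
#' @export
boundary_report <- function(predictions, truths, signals = NULL,
                            model = "detector") {
  n <- length(truths)
  if (length(predictions) != n || n == 0L) {
    stop("predictions and truths must be aligned and non-empty",
         call. = FALSE)
  }
  present <- !vapply(predictions, is.null, logical(1))
  if (!any(present)) stop("no valid predictions to report", call. = FALSE)
  dice <- vapply(seq_len(n), function(i) {
    interval_dice(predictions[[i]], truths[[i]])
  }, numeric(1))
  ps <- vapply(predictions[present], `[[`, integer(1), "start")
  pe <- vapply(predictions[present], `[[`, integer(1), "end")
  ts <- vapply(truths[present], `[[`, integer(1), "start")
  te <- vapply(truths[present], `[[`, integer(1), "end")
  safe_r2 <- function(a, b) tryCatch(r2(a, b), error = function(e) NA_real_)
  r2_vol <- NA_real_
  if (!is.null(signals)) {
    stopifnot(length(signals) == n)
    idx <- which(present)
    vol_t <- vapply(idx, function(i) {
      surrogate_volume(signals[[i]], truths[[i]])
    }, numeric(1))
    vol_p <- vapply(idx, function(i) {
      surrogate_volume(signals[[i]], predictions[[i]])
    }, numeric(1))
    r2_vol <- safe_r2(vol_t, vol_p)
  }
  data.frame(model = model,
             r2_start = safe_r2(ts, ps), r2_end = safe_r2(te, pe),
             mae_start = mae(ts, ps), mae_end = mae(te, pe),
             mse_start = mse(ts, ps), mse_end = mse(te, pe),
             dice = mean(dice), r2_volume = r2_vol,
             n = n, n_absent = sum(!present),
             stringsAsFactors = FALSE)
}
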