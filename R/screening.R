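#' Screening rule for segmentation-failure signals
#'
#' Parameters of the rolling-baseline anomaly screen: a slice is flagged when
#' its count falls below `low_frac` or rises above `high_frac` of the mean of
#' the last `window` non-anomalous slices, and an aneurysm is declared when
#' at least `persistence` consecutive slices are flagged.
#'
#' @param window baseline window length in slices, default 4.
#' @param low_frac lower relative threshold in `(0, 1)`, default 0.50.
#' @param high_frac upper relative threshold `> 1`, default 1.40.
#' @param persistence consecutive flagged slices needed to declare an
#'   anomaly (and consecutive clean slices needed to recover), default 4.
#' @return Object of class `screening_rule`.
#' @export
screening_rule <- function(window = 4L, low_frac = 0.50, high_frac = 1.40,
                           persistence = 4L) {
  stopifnot(window >= 1, persistence >= 1,
            low_frac > 0, low_frac < 1, high_frac > 1)
  structure(list(window = as.integer(window), low_frac = low_frac,
                 high_frac = high_frac, persistence = as.integer(persistence)),
            class = "screening_rule")
}

#' Screen an area signal for a persistent anomaly
#'
#' Scans the signal cranial to caudal, maintaining a rolling baseline equal
#' to the mean of the last `window` slices that were themselves not flagged
#' (so the baseline freezes at its pre-anomaly value while an anomaly is in
#' progress, rather than being dragged toward the anomalous counts). A slice
#' at position `i >= window` is flagged when its count deviates from the
#' baseline by more than the rule's relative thresholds; against a zero
#' baseline any positive count is flagged. An anomaly is declared once
#' `persistence` consecutive slices are flagged; it ends at the last flagged
#' slice before `persistence` consecutive clean slices (or the end of the
#' signal). When several anomalies occur, the longest (ties: earliest) is
#' reported.
#'
#' @param signal an [area_signal()] with `n > window + persistence`.
#' @param rule a [screening_rule()].
#' @return Object of class `screening_result`: list with `is_aneurysm`,
#'   `anomaly` ([boundary_interval()] or `NULL`), `baseline_trace` (numeric
#'   vector, `NA` for the first `window` slices) and `flagged` (logical
#'   vector).
#' @examples
#' s <- area_signal(c(rep(100, 20), rep(0, 16), rep(100, 24)))
#' screen_signal(s)$anomaly  # [20, 35]
#' @export
screen_signal <- function(signal, rule = screening_rule()) {
  stopifnot(inherits(signal, "area_signal"), inherits(rule, "screening_rule"))
  n <- signal$n
  if (n <= rule$window + rule$persistence) {
    stop("signal too short to screen: need n > window + persistence",
         call. = FALSE)
  }
  counts <- as.numeric(signal$counts)
  flagged <- logical(n)
  baseline <- rep(NA_real_, n)
  clean <- counts[seq_len(rule$window)]  # first `window` slices: never flagged
  for (i in (rule$window + 1L):n) {
    b <- mean(utils::tail(clean, rule$window))
    baseline[i] <- b
    f <- if (b == 0) {
      counts[i] > 0
    } else {
      counts[i] < rule$low_frac * b || counts[i] > rule$high_frac * b
    }
    flagged[i] <- f
    if (!f) clean <- c(clean, counts[i])
  }

  runs <- anomaly_runs(flagged, rule$persistence)
  anomaly <- NULL
  if (nrow(runs) > 0) {
    len <- runs$end - runs$start + 1L
    best <- which(len == max(len))[1]  # ties -> earliest
    anomaly <- boundary_interval(runs$start[best] - 1L, runs$end[best] - 1L)
  }
  structure(list(is_aneurysm = !is.null(anomaly), anomaly = anomaly,
                 baseline_trace = baseline, flagged = flagged),
            class = "screening_result")
}

# collapse a flag vector into declared anomaly runs: a run must open with
# >= persistence consecutive flags and closes after >= persistence
# consecutive clean slices; short clean gaps are absorbed.
#' @noRd
anomaly_runs <- function(flagged, persistence) {
  n <- length(flagged)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (flagged[i]) {
      run_len <- 0L
      j <- i
      while (j <= n && flagged[j]) { run_len <- run_len + 1L; j <- j + 1L }
      if (run_len >= persistence) {
        # declared: extend over short clean gaps
        last_flag <- j - 1L
        gap <- 0L
        while (j <= n && gap < persistence) {
          if (flagged[j]) { last_flag <- j; gap <- 0L } else gap <- gap + 1L
          j <- j + 1L
        }
        out[[length(out) + 1L]] <- c(start = i, end = last_flag)
        i <- j
      } else {
        i <- j
      }
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

#' @export
print.screening_result <- function(x, ...) {
  if (x$is_aneurysm) {
    cat(sprintf("<screening_result> aneurysm flagged, anomaly [%d, %d]\n",
                x$anomaly$start, x$anomaly$end))
  } else {
    cat("<screening_result> no aneurysm flagged\n")
  }
  invisible(x)
}

#' Confusion table for a set of screening results
#'
#' @param results list of `screening_result` objects (or any objects with an
#'   `is_aneurysm` flag).
#' @param labels logical vector of true labels (`TRUE` = aneurysm), aligned
#'   with `results`.
#' @return A [confusion_table()] with aneurysm as the positive class.
#' @export
evaluate_screening <- function(results, labels) {
  if (length(results) == 0L || length(results) != length(labels)) {
    stop("results and labels must be aligned and non-empty", call. = FALSE)
  }
  pred <- vapply(results, function(r) isTRUE(r$is_aneurysm), logical(1))
  labels <- as.logical(labels)
  confusion_table(tp = sum(pred & labels), fp = sum(pred & !labels),
                  fn = sum(!pred & labels), tn = sum(!pred & !labels))
}
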