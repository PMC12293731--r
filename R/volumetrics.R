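#' Surrogate aneurysm volume
#'
#' Sum of segmented pixel counts over the inclusive aneurysm interval. The
#' result is a unit-less pixel-slice sum that scales linearly with physical
#' lumen volume but carries no voxel-size calibration.
#'
#' @param signal an [area_signal()].
#' @param interval a [boundary_interval()] valid for `signal`.
#' @return numeric surrogate volume `>= 0`.
#' @examples
#' surrogate_volume(area_signal(rep(7, 10)), boundary_interval(3, 7))  # 35
#' @export
surrogate_volume <- function(signal, interval) {
  stopifnot(inherits(signal, "area_signal"))
  check_interval(interval, signal$n)
  sum(as.numeric(signal$counts[(interval$start + 1L):(interval$end + 1L)]))
}

#' Interpolated normal baseline under an aneurysm
#'
#' Estimates what the aorta's area profile would have been without the
#' aneurysm by joining the measured counts at the start and end slices with
#' a straight line. The baseline volume is the sum of that line over the
#' interval, which equals `(counts[start] + counts[end]) / 2 * length`
#' exactly.
#'
#' @param signal an [area_signal()].
#' @param interval a [boundary_interval()] valid for `signal`.
#' @return list with `baseline` (per-slice values over the interval) and
#'   `baseline_volume`.
#' @export
interpolated_baseline <- function(signal, interval) {
  stopifnot(inherits(signal, "area_signal"))
  check_interval(interval, signal$n)
  len <- interval_length(interval)
  a <- as.numeric(signal$counts[interval$start + 1L])
  b <- as.numeric(signal$counts[interval$end + 1L])
  baseline <- if (len == 1L) a else a + (b - a) * (0:(len - 1)) / (len - 1)
  list(baseline = baseline, baseline_volume = (a + b) / 2 * len)
}

#' Enlargement percentage
#'
#' Percentage by which the observed aneurysm volume exceeds the interpolated
#' normal baseline, relative to the observed volume:
#' `100 * (observed - baseline) / observed`.
#'
#' @param observed_volume surrogate volume over the aneurysm interval, `> 0`.
#' @param baseline_volume interpolated baseline volume, `>= 0`.
#' @return percentage (0 when observed equals baseline, 100 when the
#'   baseline vanishes).
#' @export
enlargement_percent <- function(observed_volume, baseline_volume) {
  if (!is.finite(observed_volume) || observed_volume <= 0) {
    stop("enlargement undefined for observed volume <= 0", call. = FALSE)
  }
  100 * (observed_volume - baseline_volume) / observed_volume
}

#' Volume report for one patient
#'
#' Convenience wrapper computing [surrogate_volume()],
#' [interpolated_baseline()] and [enlargement_percent()] in one pass.
#'
#' @param signal an [area_signal()].
#' @param interval a [boundary_interval()] valid for `signal`.
#' @return Object of class `volume_report`: list with `observed_volume`,
#'   `baseline_volume`, `enlargement_pct`, `interval`, `patient_id`.
#' @examples
#' s <- area_signal(c(rep(100, 5), 100, 150, 200, 150, 100, rep(100, 5)))
#' volume_report(s, boundary_interval(5, 9))
#' @export
volume_report <- function(signal, interval) {
  obs <- surrogate_volume(signal, interval)
  bl <- interpolated_baseline(signal, interval)
  structure(list(observed_volume = obs,
                 baseline_volume = bl$baseline_volume,
                 enlargement_pct = enlargement_percent(obs,
                                                       bl$baseline_volume),
                 interval = interval,
                 patient_id = signal$patient_id),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(paste0("<volume_report> %s [%d, %d]: observed %.0f, ",
                     "baseline %.0f, enlargement %.1f%%\n"),
              x$patient_id, x$interval$start, x$interval$end,
              x$observed_volume, x$baseline_volume, x$enlargement_pct))
  invisible(x)
}

#' Cohort enlargement statistics
#'
#' Sample mean, median and standard deviation (n - 1 denominator) of the
#' enlargement percentages in a set of volume reports. With a single report
#' the SD is reported as 0 and flagged by `n = 1`.
#'
#' @param reports list of [volume_report()] objects.
#' @return list with `mean`, `median`, `sd`, `n`.
#' @export
cohort_enlargement_stats <- function(reports) {
  if (length(reports) == 0L) stop("no volume reports", call. = FALSE)
  pct <- vapply(reports, `[[`, numeric(1), "enlargement_pct")
  list(mean = mean(pct), median = stats::median(pct),
       sd = if (length(pct) > 1L) stats::sd(pct) else 0,
       n = length(pct))
}
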