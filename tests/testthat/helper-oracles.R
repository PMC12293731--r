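# Independent brute-force oracles used across the suite. These deliberately
# use naive enumeration/loops so they share no code path with the package.

oracle_interval_dice <- function(pred, truth) {
  if (is.null(pred)) return(0)
  a <- seq(pred$start, pred$end)
  b <- seq(truth$start, truth$end)
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  2 * tp / (2 * tp + fp + fn)
}

oracle_r2 <- function(yt, yp) {
  rss <- 0; tss <- 0; m <- sum(yt) / length(yt)
  for (i in seq_along(yt)) {
    rss <- rss + (yt[i] - yp[i])^2
    tss <- tss + (yt[i] - m)^2
  }
  1 - rss / tss
}

oracle_mae <- function(yt, yp) {
  s <- 0
  for (i in seq_along(yt)) s <- s + abs(yt[i] - yp[i])
  s / length(yt)
}

oracle_mse <- function(yt, yp) {
  s <- 0
  for (i in seq_along(yt)) s <- s + (yt[i] - yp[i])^2
  s / length(yt)
}

oracle_bce <- function(yt, yp, eps = 1e-7) {
  s <- 0
  for (i in seq_along(yt)) {
    p <- min(max(yp[i], eps), 1 - eps)
    s <- s - (yt[i] * log(p) + (1 - yt[i]) * log(1 - p))
  }
  s / length(yt)
}

# exhaustive pair-enumeration oracle for the expert rule: tests every (i, j)
# directly against the two window conditions and returns the pair maximizing
# j - i (ties: earliest i), as an inclusive 0-based interval [i, j - 1].
oracle_detect_expert <- function(counts, window = 4L, start_frac = 1.2,
                                 end_frac = 0.8) {
  n <- length(counts)
  is_start <- function(i0) {       # i0 0-based
    if (i0 < window || i0 + window - 1L > n - 1L) return(FALSE)
    base <- mean(counts[(i0 - window + 1L):i0])  # slices i0-w .. i0-1
    all(counts[(i0 + 1L):(i0 + window)] > start_frac * base)
  }
  is_end <- function(j0) {
    if (j0 < window || j0 + window - 1L > n - 1L) return(FALSE)
    base <- mean(counts[(j0 - window + 1L):j0])
    all(counts[(j0 + 1L):(j0 + window)] < end_frac * base)
  }
  best <- NULL
  for (i0 in 0:(n - 1L)) {
    if (!is_start(i0)) next
    for (j0 in 0:(n - 1L)) {
      if (j0 <= i0 || !is_end(j0)) next
      if (is.null(best) || (j0 - i0) > (best[2] - best[1])) {
        best <- c(i0, j0)
      }
    }
  }
  if (is.null(best)) return(NULL)
  boundary_interval(best[1], best[2] - 1L)
}

# shared easy synthetic regimes
easy_cohort <- function(n = 50, seed = 7, noise = 0, shape = "plateau") {
  simulate_cohort(cohort_spec(n_patients = n,
                              peak_ratio_range = c(2, 3.5),
                              bulge_shape = shape,
                              noise_cv = noise, seed = seed))
}
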