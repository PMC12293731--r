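#' Expert sliding-window boundary rule
#'
#' Parameters of the rule-based aneurysm boundary detector: the aneurysm
#' starts where the area signal rises above `start_frac` of the preceding
#' running average consistently across `window` slices, and ends where it
#' drops below `end_frac` of the running average for `window` slices.
#'
#' @param window sliding-window length in slices, default 4.
#' @param start_frac relative rise threshold `> 1`, default 1.20.
#' @param end_frac relative drop threshold in `(0, 1)`, default 0.80.
#' @return Object of class `expert_rule`.
#' @export
expert_rule <- function(window = 4L, start_frac = 1.20, end_frac = 0.80) {
  stopifnot(window >= 1, start_frac > 1, end_frac > 0, end_frac < 1)
  structure(list(window = as.integer(window), start_frac = start_frac,
                 end_frac = end_frac), class = "expert_rule")
}

#' Detect aneurysm boundaries with the expert rule
#'
#' A candidate start `i` is a slice such that all of slices
#' `i .. i+window-1` exceed `start_frac` times the mean of the `window`
#' slices preceding `i` (the mean is anchored at the candidate, so a
#' sustained rise cannot absorb itself into its own baseline). A candidate
#' end `j` is defined symmetrically with `end_frac` as a sustained drop.
#' Among all pairs with `j > i` the pair maximizing `j - i` (the largest
#' abnormality window; ties broken toward the earliest start) is selected
#' and the interval `[i, j - 1]` is returned, covering the enlarged slices
#' only. Returns `NULL` when no rise/drop pair exists. The rule is scale
#' invariant: multiplying all counts by a positive constant changes nothing.
#'
#' @param signal an [area_signal()] with `n > 2 * window`.
#' @param rule an [expert_rule()].
#' @return A [boundary_interval()], or `NULL` when nothing is detected.
#' @examples
#' s <- area_signal(c(rep(100, 20), rep(200, 20), rep(100, 20)))
#' detect_expert(s)
#' @export
detect_expert <- function(signal, rule = expert_rule()) {
  stopifnot(inherits(signal, "area_signal"), inherits(rule, "expert_rule"))
  w <- rule$window
  n <- signal$n
  if (n <= 2L * w) {
    stop("signal too short for expert rule: need n > 2*window", call. = FALSE)
  }
  counts <- as.numeric(signal$counts)
  # anchored preceding-window means, 1-based position p has mean of p-w..p-1
  cs <- cumsum(c(0, counts))
  pos <- (w + 1L):(n - w + 1L)                 # candidate positions (1-based)
  base <- (cs[pos] - cs[pos - w]) / w
  win_min <- rolling_min(counts, w)[pos]       # min over p..p+w-1
  win_max <- rolling_max(counts, w)[pos]
  starts <- pos[win_min > rule$start_frac * base]
  ends <- pos[win_max < rule$end_frac * base]
  if (length(starts) == 0L || length(ends) == 0L) return(NULL)
  j <- max(ends)
  ok <- starts[starts < j]
  if (length(ok) == 0L) return(NULL)
  i <- min(ok)
  boundary_interval(i - 1L, j - 2L)            # back to 0-based, end = j - 1
}

#' @noRd
rolling_min <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n - w + 1L), function(p) min(x[p:(p + w - 1L)]), numeric(1))
}

#' @noRd
rolling_max <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n - w + 1L), function(p) max(x[p:(p + w - 1L)]), numeric(1))
}

#' Grid search over expert-rule parameters
#'
#' Exhaustively evaluates every combination of `window`, `start_frac` and
#' `end_frac`, scoring each rule by its mean interval Dice over the cohort
#' (an absent prediction scores 0). Ties are broken toward the smaller
#' window, then the `start_frac` nearest 1.2, then the `end_frac` nearest
#' 0.8, i.e. toward the canonical defaults.
#'
#' @param cohort list of `synthetic_patient`-like objects (each with
#'   `$signal` and `$truth`), or a list of `list(signal =, truth =)` pairs.
#' @param windows,start_fracs,end_fracs grid values.
#' @return list with `best_rule` (an [expert_rule()]), `best_score`, and
#'   `table` (a `data.frame` of every combination with its mean Dice).
#' @export
grid_search_expert <- function(cohort,
                               windows = c(3L, 4L, 5L, 6L),
                               start_fracs = c(1.10, 1.15, 1.20, 1.25,
                                               1.30, 1.40),
                               end_fracs = c(0.60, 0.70, 0.75, 0.80,
                                             0.85, 0.90)) {
  stopifnot(length(cohort) > 0, length(windows) > 0,
            length(start_fracs) > 0, length(end_fracs) > 0)
  cohort <- Filter(function(p) !is.null(p$truth), cohort)
  if (length(cohort) == 0L) {
    stop("grid search needs at least one annotated patient", call. = FALSE)
  }
  grid <- expand.grid(window = as.integer(windows),
                      start_frac = start_fracs, end_frac = end_fracs,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_dice <- vapply(seq_len(nrow(grid)), function(g) {
    rule <- expert_rule(grid$window[g], grid$start_frac[g], grid$end_frac[g])
    mean(vapply(cohort, function(p) {
      interval_dice(detect_expert(p$signal, rule), p$truth)
    }, numeric(1)))
  }, numeric(1))
  best <- order(-grid$mean_dice, grid$window,
                abs(grid$start_frac - 1.2), abs(grid$end_frac - 0.8))[1]
  list(best_rule = expert_rule(grid$window[best], grid$start_frac[best],
                               grid$end_frac[best]),
       best_score = grid$mean_dice[best],
       table = grid)
}
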