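#' Specification of a synthetic patient cohort
#'
#' Defines the generative model for synthetic per-slice aortic area signals
#' with known aneurysm boundaries. A patient's noise-free profile is a
#' linearly tapering normal aorta (area decreasing from the thoracic end
#' toward the iliac bifurcation) multiplied, inside the aneurysm interval, by
#' a fusiform bulge envelope that rises from 1 at the start slice to
#' `peak_ratio` and returns to 1 at the end slice. Multiplicative lognormal
#' noise with a given coefficient of variation emulates tracking jitter.
#' `dropout_mode` instead zeroes all counts inside the aneurysm, emulating a
#' segmentation model trained only on normal anatomy that stops producing
#' masks over the pathological region.
#'
#' @param n_patients number of patients.
#' @param n_slices_range integer `(min, max)` scan length in slices.
#' @param base_count_range normal aortic pixel count at the thoracic end.
#' @param taper_fraction linear area decrease over the scan, in `[0, 1]`.
#' @param aneurysm_prob probability that a patient has an aneurysm.
#' @param peak_ratio_range peak bulge area over local baseline, min `> 1`.
#' @param aneurysm_len_range aneurysm length in slices.
#' @param bulge_shape one of `"plateau"`, `"gaussian"`, `"asymmetric"`.
#' @param noise_cv multiplicative noise coefficient of variation, `>= 0`.
#' @param dropout_mode if `TRUE`, counts inside the aneurysm are replaced
#'   by 0 (segmentation-failure emulation).
#' @param model_bifurcation if `TRUE`, counts after a bifurcation slice near
#'   the caudal end are multiplied by `bifurcation_drop`.
#' @param bifurcation_drop multiplier in `(0, 1]` applied past the
#'   bifurcation when modeled.
#' @param seed integer cohort seed; every sampled quantity derives from it.
#' @return Object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_patients = 5, seed = 1)
#' @export
cohort_spec <- function(n_patients,
                        n_slices_range = c(120L, 200L),
                        base_count_range = c(300, 600),
                        taper_fraction = 0.15,
                        aneurysm_prob = 1.0,
                        peak_ratio_range = c(1.5, 3.5),
                        aneurysm_len_range = c(20L, 60L),
                        bulge_shape = c("plateau", "gaussian", "asymmetric"),
                        noise_cv = 0.03,
                        dropout_mode = FALSE,
                        model_bifurcation = FALSE,
                        bifurcation_drop = 0.5,
                        seed = 1L) {
  bulge_shape <- match.arg(bulge_shape)
  stopifnot(n_patients >= 1,
            length(n_slices_range) == 2, n_slices_range[1] <= n_slices_range[2],
            length(base_count_range) == 2,
            base_count_range[1] <= base_count_range[2],
            taper_fraction >= 0, taper_fraction <= 1,
            aneurysm_prob >= 0, aneurysm_prob <= 1,
            length(peak_ratio_range) == 2, peak_ratio_range[1] > 1,
            peak_ratio_range[1] <= peak_ratio_range[2],
            length(aneurysm_len_range) == 2,
            aneurysm_len_range[1] <= aneurysm_len_range[2],
            noise_cv >= 0,
            bifurcation_drop > 0, bifurcation_drop <= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    n_slices_range = as.integer(n_slices_range),
    base_count_range = as.numeric(base_count_range),
    taper_fraction = taper_fraction,
    aneurysm_prob = aneurysm_prob,
    peak_ratio_range = as.numeric(peak_ratio_range),
    aneurysm_len_range = as.integer(aneurysm_len_range),
    bulge_shape = bulge_shape,
    noise_cv = noise_cv,
    dropout_mode = isTRUE(dropout_mode),
    model_bifurcation = isTRUE(model_bifurcation),
    bifurcation_drop = bifurcation_drop,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# counter-based per-patient sub-seed: independent of cohort size, < 2^31
#' @noRd
derive_seed <- function(seed, i) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(i) * 2654435) %%
               2147483646) + 1L
}

# bulge envelope over L slices: 1 at both ends, peak in the interior
#' @noRd
bulge_envelope <- function(L, peak, shape,
                           ramp_up = 5L, ramp_down = 5L) {
  if (L == 1L) return(peak)
  k <- seq_len(L) - 1
  if (shape == "gaussian") {
    m <- (L - 1) / 2
    raw <- exp(-0.5 * ((k - m) / ((L - 1) / 6))^2)
    return(1 + (peak - 1) * (raw - raw[1]) / (1 - raw[1]))
  }
  if (shape == "plateau") ramp_down <- ramp_up
  ru <- min(ramp_up, (L - 1) %/% 2)
  rd <- min(ramp_down, L - 1 - ru)
  env <- rep(peak, L)
  if (ru > 0) {
    env[1:(ru + 1)] <- 1 + (peak - 1) * 0.5 * (1 - cos(pi * (0:ru) / ru))
  }
  if (rd > 0) {
    env[L - (rd:0)] <- 1 + (peak - 1) * 0.5 * (1 - cos(pi * (rd:0) / rd))
  }
  env
}

#' Simulate one synthetic patient
#'
#' Draws scan length, baseline area, and (if aneurysmal) bulge position,
#' length and peak ratio uniformly from the ranges in `spec`, builds the
#' noise-free tapered profile with the bulge envelope, applies multiplicative
#' lognormal noise with coefficient of variation `spec$noise_cv`, rounds to
#' non-negative integer counts, and finally applies dropout if requested.
#' All randomness derives from `seed`; repeated calls with the same spec and
#' seed return identical patients.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this patient (see [simulate_cohort()] for
#'   the cohort-level derivation).
#' @param patient_id identifier.
#' @return Object of class `synthetic_patient`: list with `signal`
#'   ([area_signal()]), `truth` ([boundary_interval()] or `NULL`),
#'   `has_aneurysm`, and `params_used`.
#' @export
simulate_patient <- function(spec, seed = spec$seed, patient_id = "P000") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- sample_range_int(spec$n_slices_range)
  base <- stats::runif(1, spec$base_count_range[1], spec$base_count_range[2])
  has_aneurysm <- stats::runif(1) < spec$aneurysm_prob
  i <- seq_len(n) - 1
  profile <- base * (1 - spec$taper_fraction * i / (n - 1))
  truth <- NULL
  params <- list(n = n, base = base, seed = seed)
  if (has_aneurysm) {
    len <- sample_range_int(spec$aneurysm_len_range)
    margin <- 10L
    if (len + 2L * margin >= n) {
      stop("aneurysm length ", len, " does not fit a scan of ", n,
           " slices with ", margin, "-slice margins", call. = FALSE)
    }
    start <- sample_range_int(c(margin, n - len - margin))
    end <- start + len - 1L
    peak <- stats::runif(1, spec$peak_ratio_range[1], spec$peak_ratio_range[2])
    env <- bulge_envelope(len, peak, spec$bulge_shape,
                          ramp_up = 5L, ramp_down = 10L)
    profile[(start + 1L):(end + 1L)] <-
      profile[(start + 1L):(end + 1L)] * env
    truth <- boundary_interval(start, end)
    params <- c(params, list(len = len, start = start, end = end,
                             peak = peak, shape = spec$bulge_shape))
  }
  if (spec$model_bifurcation) {
    bif <- floor(0.9 * n)
    profile[(bif + 1L):n] <- profile[(bif + 1L):n] * spec$bifurcation_drop
    params$bifurcation_slice <- bif
  }
  if (spec$noise_cv > 0) {
    sigma <- sqrt(log(1 + spec$noise_cv^2))
    profile <- profile * stats::rlnorm(n, meanlog = -sigma^2 / 2,
                                       sdlog = sigma)
  }
  counts <- pmax(0, round(profile))
  if (spec$dropout_mode && has_aneurysm) {
    counts[(truth$start + 1L):(truth$end + 1L)] <- 0
  }
  structure(list(signal = area_signal(counts, patient_id = patient_id),
                 truth = truth,
                 has_aneurysm = has_aneurysm,
                 params_used = params),
            class = "synthetic_patient")
}

#' @noRd
sample_range_int <- function(rng) {
  if (rng[1] == rng[2]) return(as.integer(rng[1]))
  as.integer(sample(seq.int(rng[1], rng[2]), 1))
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s: %d slices, %s\n",
              x$signal$patient_id, x$signal$n,
              if (x$has_aneurysm) {
                sprintf("aneurysm [%d, %d]", x$truth$start, x$truth$end)
              } else "no aneurysm"))
  invisible(x)
}

#' Simulate a cohort of synthetic patients
#'
#' Per-patient seeds are derived from `spec$seed` by a counter-based mixing
#' scheme, so patient `i` is identical regardless of cohort size and two runs
#' with the same spec produce identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list of `synthetic_patient` objects, length `spec$n_patients`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 3, seed = 42))
#' sapply(cohort, function(p) p$signal$n)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_patients), function(i) {
    simulate_patient(spec, seed = derive_seed(spec$seed, i),
                     patient_id = sprintf("P%03d", i))
  })
}

#' Rasterize a synthetic patient into a mask stack
#'
#' Builds one binary slice per count: a centered filled disc whose rasterized
#' pixel count equals the signal count exactly. Exactness is achieved by
#' ranking pixels by distance from the (slightly tie-broken) slice center and
#' filling exactly `count` nearest pixels, which is a thresholded radial
#' distance and hence a disc.
#'
#' @param patient a `synthetic_patient` (or any object with `$signal`).
#' @param side slice height = width in pixels; defaults to the smallest
#'   comfortable square holding the largest disc.
#' @return A [mask_stack()].
#' @export
rasterize_patient <- function(patient, side = NULL) {
  signal <- patient$signal
  stopifnot(inherits(signal, "area_signal"))
  if (is.null(side)) {
    side <- as.integer(ceiling(2 * sqrt(max(signal$counts, 1) / pi)) + 6L)
  }
  side <- as.integer(side)
  if (max(signal$counts) > side^2) {
    stop("count ", max(signal$counts), " exceeds slice area ", side^2,
         call. = FALSE)
  }
  cx <- (side + 1) / 2 + 0.1234   # small offsets break distance ties
  cy <- (side + 1) / 2 + 0.0567
  d2 <- outer((seq_len(side) - cy)^2, (seq_len(side) - cx)^2, `+`)
  ord <- order(d2)
  slices <- lapply(signal$counts, function(cnt) {
    m <- matrix(0L, side, side)
    if (cnt > 0) m[ord[seq_len(cnt)]] <- 1L
    m
  })
  mask_stack(slices, patient_id = signal$patient_id)
}

#' Write a cohort to disk
#'
#' Emits one signal CSV per patient (see [write_signal_table()]) plus a
#' cohort manifest `manifest.csv` with columns
#' `patient_id,n_slices,has_aneurysm,start,end,seed`, and optionally one
#' multi-page TIFF mask stack per patient.
#'
#' @param cohort list of `synthetic_patient` objects.
#' @param dir output directory (created if needed).
#' @param masks if `TRUE`, also write rasterized mask stacks.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(p) {
    write_signal_table(p$signal,
                       file.path(dir, paste0(p$signal$patient_id, ".csv")))
    if (masks) {
      write_mask_stack(rasterize_patient(p),
                       file.path(dir, paste0(p$signal$patient_id, ".tif")))
    }
    data.frame(patient_id = p$signal$patient_id,
               n_slices = p$signal$n,
               has_aneurysm = p$has_aneurysm,
               start = if (p$has_aneurysm) p$truth$start else NA_integer_,
               end = if (p$has_aneurysm) p$truth$end else NA_integer_,
               seed = p$params_used$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and per-patient CSVs.
#' @return list of `synthetic_patient`-shaped objects (signal, truth,
#'   has_aneurysm).
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) {
    stop("no cohort manifest at ", path, call. = FALSE)
  }
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    structure(list(
      signal = read_signal_table(file.path(dir, paste0(row$patient_id, ".csv")),
                                 patient_id = row$patient_id),
      truth = if (isTRUE(row$has_aneurysm)) {
        boundary_interval(row$start, row$end)
      } else NULL,
      has_aneurysm = isTRUE(row$has_aneurysm),
      params_used = list(seed = row$seed)
    ), class = "synthetic_patient")
  })
}
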