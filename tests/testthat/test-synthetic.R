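test_that("noise-free plateau patients are exact piecewise profiles", {
  spec <- cohort_spec(n_patients = 1, n_slices_range = c(150, 150),
                      base_count_range = c(400, 400), taper_fraction = 0,
                      peak_ratio_range = c(2, 2), aneurysm_len_range = c(40, 40),
                      bulge_shape = "plateau", noise_cv = 0, seed = 21)
  p <- simulate_patient(spec)
  truth <- p$truth
  expect_equal(truth$end - truth$start + 1L, 40L)
  counts <- p$signal$counts
  outside <- setdiff(seq_len(150), (truth$start + 1):(truth$end + 1))
  expect_true(all(counts[outside] == 400L))
  # flat top between the 5-slice raised-cosine ramps
  top <- (truth$start + 6):(truth$end - 4)
  expect_true(all(counts[top] == 800L))
  # envelope strictly exceeds baseline on the open interior
  interior <- (truth$start + 2):(truth$end)
  expect_true(all(counts[interior] > 400L))
  # endpoints sit on the baseline
  expect_equal(counts[truth$start + 1], 400L)
  expect_equal(counts[truth$end + 1], 400L)
})

test_that("dropout mode zeroes exactly the aneurysm interval", {
  spec <- cohort_spec(n_patients = 1, n_slices_range = c(150, 150),
                      base_count_range = c(400, 400), taper_fraction = 0,
                      peak_ratio_range = c(2, 2), aneurysm_len_range = c(40, 40),
                      bulge_shape = "plateau", noise_cv = 0,
                      dropout_mode = TRUE, seed = 21)
  p <- simulate_patient(spec)
  idx <- (p$truth$start + 1):(p$truth$end + 1)
  expect_true(all(p$signal$counts[idx] == 0L))
  expect_true(all(p$signal$counts[-idx] == 400L))
})

test_that("cohorts are pure functions of their spec (seed included)", {
  spec <- cohort_spec(n_patients = 8, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(lapply(a, function(p) p$signal$counts),
                   lapply(b, function(p) p$signal$counts))
  expect_identical(lapply(a, `[[`, "truth"), lapply(b, `[[`, "truth"))
  # patient i does not depend on cohort size
  small <- simulate_cohort(cohort_spec(n_patients = 3, seed = 99))
  expect_identical(small[[2]]$signal$counts, a[[2]]$signal$counts)
})

test_that("aneurysm_prob controls the aneurysm mix", {
  all_pos <- simulate_cohort(cohort_spec(n_patients = 20, seed = 5))
  expect_true(all(vapply(all_pos, `[[`, logical(1), "has_aneurysm")))
  none <- simulate_cohort(cohort_spec(n_patients = 20, aneurysm_prob = 0,
                                      seed = 5))
  expect_false(any(vapply(none, `[[`, logical(1), "has_aneurysm")))
  expect_true(all(vapply(none, function(p) is.null(p$truth), logical(1))))
})

test_that("sampled peak ratios are uniform over their range", {
  cohort <- simulate_cohort(cohort_spec(n_patients = 400,
                                        peak_ratio_range = c(1.5, 3.5),
                                        seed = 13))
  peaks <- vapply(cohort, function(p) p$params_used$peak, numeric(1))
  expect_true(all(peaks > 1.5 & peaks < 3.5))
  # mean near the midpoint 2.5 within Monte-Carlo error (sd/sqrt(n) ~ 0.029)
  expect_lt(abs(mean(peaks) - 2.5), 0.12)
})

test_that("all bulge shapes keep endpoints on the baseline and bulge inside", {
  for (shape in c("plateau", "gaussian", "asymmetric")) {
    spec <- cohort_spec(n_patients = 1, n_slices_range = c(160, 160),
                        base_count_range = c(500, 500), taper_fraction = 0.15,
                        peak_ratio_range = c(2.5, 2.5),
                        aneurysm_len_range = c(30, 30), bulge_shape = shape,
                        noise_cv = 0, seed = 31)
    p <- simulate_patient(spec)
    n <- p$signal$n
    base_profile <- 500 * (1 - 0.15 * (0:(n - 1)) / (n - 1))
    counts <- as.numeric(p$signal$counts)
    inside <- (p$truth$start + 2):p$truth$end
    outside <- setdiff(seq_len(n), (p$truth$start + 1):(p$truth$end + 1))
    expect_true(all(counts[inside] > base_profile[inside]), label = shape)
    expect_true(all(abs(counts[outside] - base_profile[outside]) <= 0.5),
                label = shape)
  }
})

test_that("oversized aneurysms are rejected", {
  spec <- cohort_spec(n_patients = 1, n_slices_range = c(60, 60),
                      aneurysm_len_range = c(55, 55), seed = 1)
  expect_error(simulate_patient(spec), "does not fit")
})

test_that("cohort write/read round-trips signals and truth", {
  cohort <- simulate_cohort(cohort_spec(n_patients = 4, aneurysm_prob = 0.5,
                                        seed = 17))
  dir <- tempfile()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(lapply(back, function(p) p$signal$counts),
                   lapply(cohort, function(p) p$signal$counts))
  expect_identical(lapply(back, `[[`, "truth"),
                   lapply(cohort, `[[`, "truth"))
})
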