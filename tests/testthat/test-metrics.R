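test_that("interval Dice matches slice-set enumeration", {
  a <- boundary_interval(10, 20); b <- boundary_interval(15, 25)
  expect_equal(interval_dice(a, b), 12 / 22)
  expect_equal(interval_dice(a, a), 1)
  expect_equal(interval_dice(boundary_interval(0, 4),
                             boundary_interval(10, 14)), 0)
  expect_equal(interval_dice(NULL, b), 0)
  # symmetry and identity-only perfection over random intervals
  set.seed(5)
  for (i in 1:200) {
    p <- sort(sample(0:60, 2)); t <- sort(sample(0:60, 2))
    ip <- boundary_interval(p[1], p[2]); it <- boundary_interval(t[1], t[2])
    d <- interval_dice(ip, it)
    expect_equal(d, oracle_interval_dice(ip, it))
    expect_equal(d, interval_dice(it, ip))
    if (d == 1) expect_identical(unclass(ip), unclass(it))
  }
})

test_that("regression metrics agree with brute-force loops", {
  yt <- c(1, 2, 3, 4); yp <- c(2, 2, 3, 3)
  expect_equal(r2(yt, yp), 0.6)
  expect_equal(mae(yt, yp), 0.5)
  expect_equal(mse(yt, yp), 0.5)
  expect_equal(r2(yt, yt), 1)
  expect_equal(r2(yt, rep(mean(yt), 4)), 0)
  expect_error(r2(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r2(1, 1), "n >= 2")
  # constant offset closed form
  expect_equal(mae(yt, yt + 3), 3)
  expect_equal(mse(yt, yt - 2), 4)
  set.seed(6)
  for (i in 1:150) {
    n <- sample(2:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    if (stats::var(a) == 0) next
    expect_equal(r2(a, b), oracle_r2(a, b), tolerance = 1e-12)
    expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
    expect_equal(mse(a, b), oracle_mse(a, b), tolerance = 1e-12)
  }
})

test_that("binary cross-entropy is clipped and matches the definition", {
  expect_equal(bce(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce(1, 0.5), log(2), tolerance = 1e-12)
  yt <- c(0, 1, 1, 0, 1)
  expect_equal(bce(yt, rep(0.5, 5)), log(2), tolerance = 1e-12)
  expect_true(is.finite(bce(c(0, 1), c(1, 0))))  # clipping guards the log
  expect_error(bce(c(0, 0.5), c(0.2, 0.3)), "binary")
  set.seed(8)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    yt <- rbinom(n, 1, 0.5); yp <- runif(n)
    expect_equal(bce(yt, yp), oracle_bce(yt, yp), tolerance = 1e-12)
  }
})

test_that("mse and mae relate as expected in the equal-error case", {
  y <- c(1, 5, 9, 2)
  expect_equal(mse(y, y + 2), mae(y, y + 2)^2)  # all |e| equal
  expect_gte(mse(y, c(2, 5, 9, 2)), 0)
  expect_gte(mae(y, c(2, 5, 9, 2)), 0)
})

test_that("classification metrics handle scaling and zero denominators", {
  cm <- confusion_table(tp = 15, fp = 2, fn = 2, tn = 14)
  m <- classification_metrics(cm)
  expect_equal(round(m$accuracy, 3), 0.879)
  expect_equal(round(m$precision, 3), 0.882)
  expect_equal(round(m$recall, 3), 0.882)
  expect_equal(round(m$specificity, 3), 0.875)
  expect_equal(round(m$f1, 3), 0.882)
  # perfect diagonal
  perfect <- classification_metrics(confusion_table(5, 0, 0, 5))
  expect_true(all(unlist(perfect) == 1))
  # uniform table
  u <- classification_metrics(confusion_table(1, 1, 1, 1))
  expect_true(all(unlist(u) == 0.5))
  # count-scale invariance
  m3 <- classification_metrics(confusion_table(45, 6, 6, 42))
  expect_equal(m, m3)
  # undefined metrics are NA, not zero
  no_pos <- classification_metrics(confusion_table(0, 0, 0, 10))
  expect_true(is.na(no_pos$precision))
  expect_true(is.na(no_pos$recall))
  expect_equal(no_pos$accuracy, 1)
})

test_that("boundary report reproduces closed-form shift errors", {
  cohort <- easy_cohort(n = 10, seed = 41, noise = 0)
  truths <- lapply(cohort, `[[`, "truth")
  signals <- lapply(cohort, `[[`, "signal")
  perfect <- boundary_report(truths, truths, signals, model = "perfect")
  expect_equal(perfect$dice, 1)
  expect_equal(perfect$mae_start, 0)
  expect_equal(perfect$mse_end, 0)
  expect_equal(perfect$r2_start, 1)
  expect_equal(perfect$r2_volume, 1)

  shifted <- lapply(truths, function(t) {
    boundary_interval(t$start + 5, t$end + 5)
  })
  rep5 <- boundary_report(shifted, truths, signals, model = "shift5")
  expect_equal(rep5$mae_start, 5)
  expect_equal(rep5$mse_start, 25)
  ts <- vapply(truths, `[[`, integer(1), "start")
  expect_equal(rep5$r2_start, r2(ts, ts + 5))

  # absent predictions: Dice 0, excluded from regressions, counted
  some <- truths; some[1] <- list(NULL)
  repa <- boundary_report(some, truths, signals)
  expect_equal(repa$n_absent, 1)
  expect_equal(repa$dice, 9 / 10)
  expect_equal(repa$mae_start, 0)
  expect_named(repa, c("model", "r2_start", "r2_end", "mae_start", "mae_end",
                       "mse_start", "mse_end", "dice", "r2_volume",
                       "n", "n_absent"))
  expect_error(boundary_report(list(NULL, NULL), truths[1:2], signals[1:2]),
               "no valid predictions")
})
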