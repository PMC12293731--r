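test_that("input encoding resamples, rescales, and guards degenerate input", {
  # n == out_len: identity resampling, scaled by the max
  s <- area_signal(c(100, 300, 200, 400), "t")
  enc <- encode_input(s, out_len = 4)
  expect_equal(enc$x, c(100, 300, 200, 400) / 400)
  # all-zero signal passes through without division
  z <- encode_input(area_signal(rep(0, 10)), out_len = 5)
  expect_equal(z$x, rep(0, 5))
  expect_error(encode_input(area_signal(5), 4), "at least 2")
  # values always normalized to [0, 1]
  big <- area_signal(sample(0:5000, 137))
  expect_true(all(encode_input(big)$x <= 1 & encode_input(big)$x >= 0))
})

test_that("target encoding and run decoding invert the position map", {
  # n = 400 compressed to 200 positions: slices [100,199] <-> positions [50,99]
  t <- encode_target(boundary_interval(100, 199), n = 400, out_len = 200)
  expect_equal(which(t == 1) - 1, 50:99)
  back <- aaaquant:::decode_positions(50, 99, n = 400, out_len = 200)
  expect_equal(unclass(back), list(start = 100L, end = 199L))

  expect_equal(sum(encode_target(boundary_interval(0, 399), 400, 200)), 200)
  expect_equal(sum(encode_target(NULL, 400, 200)), 0)

  # round trip within the resampling quantum ceil(n / out_len)
  set.seed(12)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    a <- sort(sample(0:(n - 1), 2))
    iv <- boundary_interval(a[1], a[2])
    tgt <- encode_target(iv, n, 200)
    if (!any(tgt == 1)) next  # interval narrower than one position block
    run <- range(which(tgt == 1)) - 1
    dec <- aaaquant:::decode_positions(run[1], run[2], n, 200)
    q <- ceiling(n / 200)
    expect_lte(abs(dec$start - iv$start), q)
    expect_lte(abs(dec$end - iv$end), q)
  }
})

test_that("analytic gradients match central differences", {
  set.seed(2)
  w <- aaaquant:::lstm_init_cpp(5L, 3L, 2L, c(4L), 1L)
  X <- matrix(runif(3 * 9), 3, 9)
  Y <- matrix(rbinom(27, 1, 0.4), 3, 9)
  g <- aaaquant:::lstm_gradient_cpp(w, X, Y, 1.0)
  eps <- 1e-5
  for (nm in names(w)) {
    pick <- unique(round(seq(1, length(w[[nm]]), length.out = 5)))
    for (idx in pick) {
      wp <- w; wp[[nm]][idx] <- wp[[nm]][idx] + eps
      wm <- w; wm[[nm]][idx] <- wm[[nm]][idx] - eps
      num <- (aaaquant:::lstm_loss_cpp(wp, X, Y, 1) -
              aaaquant:::lstm_loss_cpp(wm, X, Y, 1)) / (2 * eps)
      scaled <- abs(g[[nm]][idx] - num) / max(1, abs(g[[nm]][idx]) + abs(num))
      expect_lt(scaled, 1e-7, label = sprintf("%s[%d] gradient error", nm, idx))
    }
  }
})

test_that("a small model overfits a tiny repeated cohort", {
  spec <- cohort_spec(n_patients = 1, n_slices_range = c(150, 150),
                      peak_ratio_range = c(2.5, 2.5), noise_cv = 0,
                      bulge_shape = "plateau", seed = 8)
  p <- simulate_patient(spec)
  cohort <- rep(list(p), 10)
  cfg <- lstm_config(hidden_units = 16L, head_layers = c(16L),
                     batch_size = 5L, max_epochs = 300L, patience = 300L,
                     seed = 4L)
  model <- train_lstm(cohort, cfg)
  expect_lt(min(model$log$train_loss), 0.1)
  # and reproduces the interval it was trained on
  pred <- predict_lstm(model, p$signal)
  expect_gte(interval_dice(pred$interval, p$truth), 0.9)
})

test_that("training is deterministic given the config seed", {
  cohort <- easy_cohort(n = 24, seed = 15, noise = 0.03)
  cfg <- lstm_config(hidden_units = 8L, head_layers = c(8L),
                     max_epochs = 5L, patience = 5L, seed = 77L)
  a <- train_lstm(cohort, cfg)
  b <- train_lstm(cohort, cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$weights, b$weights)
})

test_that("prediction takes the longest run and respects the threshold", {
  cfg <- lstm_config(hidden_units = 8L, seed = 1L)
  # synthetic probability vector exercises the run logic directly
  probs <- rep(0.1, 200)
  probs[51:80] <- 0.9   # length 30
  probs[101:110] <- 0.9 # length 10
  run <- aaaquant:::longest_run(probs > 0.5)
  expect_equal(run, c(51, 80))
  expect_null(aaaquant:::longest_run(probs > 0.95))
  # threshold monotonicity: raising the threshold never lengthens the run
  set.seed(30)
  pv <- stats::runif(200)
  lens <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    r <- aaaquant:::longest_run(pv > th)
    if (is.null(r)) 0L else r[2] - r[1] + 1L
  }, integer(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("cross-validation partitions patients exactly once", {
  cohort <- easy_cohort(n = 60, seed = 44, noise = 0.03)
  cfg <- lstm_config(seed = 10L)
  set.seed(aaaquant:::derive_seed(cfg$seed, 32452843L))
  folds <- sample(rep_len(seq_len(5L), 60))
  expect_equal(as.integer(table(folds)), rep(12L, 5))
  expect_equal(length(folds), 60)
  expect_error(crossvalidate_lstm(cohort, cfg, k = 1), "k >= 2")
  expect_error(train_lstm(cohort[1:5], lstm_config(batch_size = 10L)),
               "2 \\* batch_size")
})
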