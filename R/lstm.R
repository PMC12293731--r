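#' Configuration of the bidirectional LSTM boundary labeler
#'
#' Defaults follow the reference training protocol: two stacked
#' bidirectional LSTM layers of 600 hidden units each, a fully connected
#' ReLU head shared across the 200 output positions, a sigmoid output with a
#' fixed 0.5 classification threshold, Adam with learning rate 0.0003 and
#' batch size 10, and binary cross-entropy combined with a soft-Jaccard
#' term. `hidden_units` and the epoch budget can be scaled down for CPU-only
#' experimentation without changing the protocol.
#'
#' @param hidden_units LSTM hidden units per direction, default 600.
#' @param num_layers stacked bidirectional layers, default 2.
#' @param head_layers widths of the fully connected head, default
#'   `c(256, 64)` (a final 1-unit logit layer is always appended).
#' @param out_len model positions covering the scan, default 200.
#' @param threshold per-position classification threshold in `(0, 1)`.
#' @param lr Adam learning rate, default 0.0003.
#' @param batch_size minibatch size, default 10.
#' @param max_epochs epoch budget, default 1000.
#' @param patience early-stopping patience on validation loss, default 50.
#' @param jaccard_weight weight of the soft-Jaccard loss term, default 1.
#' @param val_fraction fraction of training patients held out for
#'   early-stopping validation, default 0.2.
#' @param seed integer seed governing initialization, the train/validation
#'   split and batch shuffling.
#' @return Object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 600L, num_layers = 2L,
                        head_layers = c(256L, 64L), out_len = 200L,
                        threshold = 0.5, lr = 3e-4, batch_size = 10L,
                        max_epochs = 1000L, patience = 50L,
                        jaccard_weight = 1.0, val_fraction = 0.2,
                        seed = 1L) {
  stopifnot(hidden_units >= 1, num_layers >= 1, out_len >= 2,
            threshold > 0, threshold < 1, lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, jaccard_weight >= 0,
            val_fraction > 0, val_fraction < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 num_layers = as.integer(num_layers),
                 head_layers = as.integer(head_layers),
                 out_len = as.integer(out_len),
                 threshold = threshold, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 jaccard_weight = jaccard_weight,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Encode an area signal as a fixed-length model input
#'
#' Linearly resamples the counts at `out_len` positions (position `p`
#' samples the signal at slice `(p + 0.5) * n / out_len - 0.5`, the center
#' of the p-th block of slices) and scales by the signal maximum so the
#' input is in `[0, 1]` regardless of aortic size. An all-zero signal is
#' passed through unscaled.
#'
#' @param signal an [area_signal()] with `n >= 2`.
#' @param out_len number of model positions, default 200.
#' @return list with `x` (numeric vector of length `out_len`) and `mapping`
#'   (`list(n, out_len)` describing the position/slice correspondence).
#' @export
encode_input <- function(signal, out_len = 200L) {
  stopifnot(inherits(signal, "area_signal"))
  if (signal$n < 2L) stop("need at least 2 slices to encode", call. = FALSE)
  n <- signal$n
  centers <- pmin(pmax((seq_len(out_len) - 0.5) * n / out_len - 0.5, 0),
                  n - 1)
  x <- stats::approx(x = 0:(n - 1), y = as.numeric(signal$counts),
                     xout = centers)$y
  mx <- max(x)
  if (mx > 0) x <- x / mx
  list(x = x, mapping = list(n = n, out_len = as.integer(out_len)))
}

#' Encode a boundary interval as a binary target sequence
#'
#' Position `p` is labeled 1 exactly when its block-center slice
#' `(p + 0.5) * n / out_len - 0.5` lies inside the inclusive interval.
#'
#' @param truth a [boundary_interval()] or `NULL` (no aneurysm: all-zero
#'   target).
#' @param n number of slices in the original signal.
#' @param out_len number of model positions, default 200.
#' @return binary numeric vector of length `out_len`.
#' @export
encode_target <- function(truth, n, out_len = 200L) {
  if (is.null(truth)) return(numeric(out_len))
  check_interval(truth, n)
  centers <- (seq_len(out_len) - 0.5) * n / out_len - 0.5
  as.numeric(centers >= truth$start & centers <= truth$end)
}

# map a run of model positions [p1, p2] (0-based) back to slice indices
#' @noRd
decode_positions <- function(p1, p2, n, out_len) {
  start <- ceiling(p1 * n / out_len - 0.5)
  end <- floor((p2 + 1) * n / out_len - 0.5)
  start <- max(0L, min(as.integer(start), n - 1L))
  end <- max(start, min(as.integer(end), n - 1L))
  boundary_interval(start, end)
}

#' Train the bidirectional LSTM labeler
#'
#' Encodes every patient signal and truth interval to length
#' `cfg$out_len`, holds out a patient-level validation split, and runs
#' minibatch Adam on binary cross-entropy plus `cfg$jaccard_weight` times
#' `(1 - softJaccard)` per sequence, where
#' `softJaccard = sum(p*t) / sum(p + t - p*t)`. Training stops at
#' `cfg$max_epochs` or after `cfg$patience` epochs without validation
#' improvement; the best-validation weights are returned. All randomness
#' (weight init, split, shuffling) derives from `cfg$seed`.
#'
#' @param cohort list of `synthetic_patient`-like objects (each with
#'   `$signal` and `$truth`, the latter possibly `NULL`).
#' @param cfg an [lstm_config()].
#' @return Object of class `lstm_model`: list with `weights`, `cfg`, and
#'   `log` (data.frame of per-epoch train/validation loss).
#' @export
train_lstm <- function(cohort, cfg = lstm_config()) {
  stopifnot(inherits(cfg, "lstm_config"))
  if (length(cohort) < 2L * cfg$batch_size) {
    stop("need at least 2 * batch_size training patients", call. = FALSE)
  }
  enc <- encode_cohort(cohort, cfg$out_len)
  n_pat <- nrow(enc$X)
  # patient-level validation split
  set.seed(derive_seed(cfg$seed, 7919L))
  n_val <- max(1L, round(cfg$val_fraction * n_pat))
  val_idx <- sample(n_pat, n_val)
  weights <- lstm_init_cpp(derive_seed(cfg$seed, 104729L),
                           cfg$hidden_units, cfg$num_layers,
                           cfg$head_layers, 1L)
  fit <- lstm_train_cpp(weights,
                        enc$X[-val_idx, , drop = FALSE],
                        enc$Y[-val_idx, , drop = FALSE],
                        enc$X[val_idx, , drop = FALSE],
                        enc$Y[val_idx, , drop = FALSE],
                        cfg$lr, cfg$batch_size, cfg$max_epochs,
                        cfg$patience, cfg$jaccard_weight,
                        derive_seed(cfg$seed, 15485863L))
  log <- data.frame(epoch = seq_along(fit$train_loss),
                    train_loss = fit$train_loss,
                    val_loss = fit$val_loss)
  structure(list(weights = fit$weights, cfg = cfg, log = log,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(paste0("<lstm_model> %d x BiLSTM(%d), trained %d epochs ",
                     "(best %d, val loss %.4f)\n"),
              x$cfg$num_layers, x$cfg$hidden_units, nrow(x$log),
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @noRd
encode_cohort <- function(cohort, out_len) {
  X <- t(vapply(cohort, function(p) encode_input(p$signal, out_len)$x,
                numeric(out_len)))
  Y <- t(vapply(cohort, function(p) {
    encode_target(p$truth, p$signal$n, out_len)
  }, numeric(out_len)))
  list(X = X, Y = Y)
}

#' Predict aneurysm boundaries with a trained LSTM
#'
#' Runs the model on one signal, thresholds the per-position probabilities
#' at `model$cfg$threshold`, takes the longest contiguous positive run
#' (ties: earliest) and maps it back to original slice indices. Returns
#' `NULL` as the interval when no position exceeds the threshold.
#'
#' @param model an `lstm_model` from [train_lstm()].
#' @param signal an [area_signal()].
#' @return list with `probs` (length `out_len`) and `interval`
#'   (a [boundary_interval()] or `NULL`).
#' @export
predict_lstm <- function(model, signal) {
  stopifnot(inherits(model, "lstm_model"))
  enc <- encode_input(signal, model$cfg$out_len)
  probs <- as.numeric(lstm_forward_cpp(model$weights,
                                       matrix(enc$x, nrow = 1)))
  run <- longest_run(probs > model$cfg$threshold)
  interval <- if (is.null(run)) NULL else {
    decode_positions(run[1] - 1L, run[2] - 1L, signal$n, model$cfg$out_len)
  }
  list(probs = probs, interval = interval)
}

# longest TRUE run (1-based first/last); ties -> earliest; NULL if none
#' @noRd
longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  best <- pos[which.max(r$lengths[pos])]
  c(starts[best], ends[best])
}

#' Patient-level k-fold cross-validation of the LSTM labeler
#'
#' Partitions patients into `k` folds (deterministically from `cfg$seed`),
#' trains on `k - 1` folds (with the internal validation split for early
#' stopping) and evaluates boundary and volume agreement on the held-out
#' fold. No patient appears in two folds.
#'
#' @param cohort list of `synthetic_patient`-like objects with non-`NULL`
#'   `$truth`.
#' @param cfg an [lstm_config()].
#' @param k number of folds, default 5 (must be `>= 2`).
#' @return list with `per_fold` (one [boundary_report()] row per fold),
#'   `pooled` (single report over all held-out predictions), `folds`
#'   (fold assignment vector) and `models`.
#' @export
crossvalidate_lstm <- function(cohort, cfg = lstm_config(), k = 5L) {
  if (k < 2L) stop("k-fold cross-validation needs k >= 2", call. = FALSE)
  n <- length(cohort)
  if (n < k) stop("need at least k patients", call. = FALSE)
  set.seed(derive_seed(cfg$seed, 32452843L))
  folds <- sample(rep_len(seq_len(k), n))
  predictions <- vector("list", n)
  per_fold <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    model <- train_lstm(cohort[folds != f], cfg)
    models[[f]] <- model
    for (i in test_idx) {
      predictions[[i]] <- predict_lstm(model, cohort[[i]]$signal)$interval
    }
    per_fold[[f]] <- boundary_report(predictions[test_idx],
                                     lapply(cohort[test_idx], `[[`, "truth"),
                                     lapply(cohort[test_idx], `[[`, "signal"),
                                     model = sprintf("lstm_fold%d", f))
  }
  pooled <- boundary_report(predictions,
                            lapply(cohort, `[[`, "truth"),
                            lapply(cohort, `[[`, "signal"),
                            model = "lstm_pooled")
  list(per_fold = do.call(rbind, per_fold), pooled = pooled,
       folds = folds, models = models)
}
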