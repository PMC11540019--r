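test_that("the calcium kernel has the double-exponential shape", {
  k <- gcamp_kernel(tau_rise = 0.2, tau_decay = 2.6, duration = 10,
                    rate = 100, peak_amplitude = 1)
  expect_equal(length(k), 1000)
  expect_equal(k[1], 0)                      # rise factor vanishes at t = 0
  expect_true(all(k >= 0))
  # peak location: analytic tau_rise * log(1 + tau_decay / tau_rise)
  t_pk <- (which.max(k) - 1) / 100
  expect_lt(abs(t_pk - 0.2 * log(1 + 2.6 / 0.2)), 0.011)
  expect_lt(abs(max(k) - 1), 1e-3)           # unit peak up to discretization
  # unimodal: increases then decreases
  d <- diff(k)
  expect_true(all(d[seq_len(which.max(k) - 1)] > 0))
  expect_true(all(d[which.max(k):length(d)] < 0))
  expect_error(gcamp_kernel(tau_rise = 3, tau_decay = 2),
               class = "needmot_kernel_error")
})

test_that("predict_signal is a causal convolution plus offset", {
  k <- gcamp_kernel(rate = 50, duration = 4)
  # zero latent: constant offset
  z <- latent_trace(rep(0, 500), rate = 50)
  expect_equal(predict_signal(z, k, offset = 0.3, mode = "none"),
               rep(0.3, 500))
  # unit impulse reproduces the kernel at the impulse lag
  imp <- latent_trace(c(rep(0, 10), 1, rep(0, 489)), rate = 50)
  out <- predict_signal(imp, k, mode = "none")
  expect_equal(out[11:(10 + length(k))], as.numeric(k), tolerance = 1e-9)
  expect_true(all(abs(out[1:10]) < 1e-9))    # causality
  # step latent matches a direct-summation oracle
  set.seed(1)
  x <- c(rep(0.5, 200), rep(1.5, 300))
  lat <- latent_trace(x, rate = 50)
  direct <- vapply(seq_along(x), function(i) {
    j <- seq_len(min(i, length(k)))
    sum(k[j] * x[i - j + 1])
  }, numeric(1))
  expect_lt(max(abs(predict_signal(lat, k, mode = "none") - direct)), 1e-9)
})

test_that("predict_signal is linear in the latent", {
  k <- gcamp_kernel(rate = 50, duration = 4)
  set.seed(2)
  x <- latent_trace(rnorm(400), rate = 50)
  y <- latent_trace(rnorm(400), rate = 50)
  combo <- latent_trace(2 * trace_values(x) - 3 * trace_values(y),
                        rate = 50)
  lhs <- predict_signal(combo, k, mode = "none")
  rhs <- 2 * predict_signal(x, k, mode = "none") -
    3 * predict_signal(y, k, mode = "none")
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("boundary modes pad with the early mean or crop the first 5 s", {
  k <- gcamp_kernel(rate = 20, duration = 4)
  lat <- latent_trace(rep(1, 300), rate = 20)
  # constant latent: pad equals the signal, so the onset ramp disappears
  padded <- predict_signal(lat, k, mode = "pad_mean")
  bare <- predict_signal(lat, k, mode = "none")
  expect_gt(bare[2], 0)
  expect_gt(padded[1], bare[1])              # history filled in
  crop <- predict_signal(lat, k, mode = "crop_last5s")
  expect_equal(length(crop), 300 - 100)
  expect_equal(crop, bare[-(1:100)])
  expect_error(predict_signal(latent_trace(1:10, rate = 20), k,
                              mode = "none"),
               class = "needmot_window_error")
})

test_that("preprocessing aligns, z-scores and up-samples to 100 Hz", {
  set.seed(3)
  t_raw <- seq(0, 40, by = 0.05)             # 20 samples/s
  raw <- do.call(rbind, lapply(1:2, function(id) {
    data.frame(trial_id = id, time_s = t_raw,
               value = sin(t_raw / 3) + rnorm(length(t_raw), 0, 0.1))
  }))
  events <- do.call(rbind, lapply(1:2, function(id) {
    data.frame(trial_id = id, event_label = c("door", "seek"),
               event_kind = c("accessibility", "gain"),
               time_s = c(5, 8))
  }))
  trials <- preprocess_trials(raw, events, "door", window = c(0, 30))
  expect_length(trials, 2)
  v <- trials[[1]]$value
  expect_equal(length(v), 3000)              # 100 Hz x 30 s
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sd(v) - 1), 1e-9)
  # missing alignment event errors
  expect_error(preprocess_trials(raw, events, "nope", c(0, 30)),
               class = "needmot_alignment_error")
  # window exceeding the recording errors
  expect_error(preprocess_trials(raw, events, "door", c(-10, 30)),
               class = "needmot_window_error")
})

test_that("constant raw traces z-score to zeros with a warning", {
  raw <- data.frame(trial_id = 1, time_s = seq(0, 10, 0.1), value = 2)
  events <- data.frame(trial_id = 1, event_label = "e0",
                       event_kind = "gain", time_s = 2)
  expect_warning(trials <- preprocess_trials(raw, events, "e0", c(-1, 5)),
                 "Zero-variance")
  expect_true(all(trials[[1]]$value == 0))
})

test_that("trial averaging is a pointwise mean with consensus events", {
  s <- template_schedule("gain1")
  mk <- function(v) photometry_trial(v, rate = 10, schedule = s)
  one <- mk(sin(1:150))
  expect_equal(average_trials(list(one))$value, one$value)
  # mirror-image traces cancel
  two <- average_trials(list(mk(sin(1:150)), mk(-sin(1:150))))
  expect_true(all(two$value == 0))
  # residual noise shrinks like 1/sqrt(n) under averaging
  set.seed(4)
  base <- sin((1:150) / 10)
  noisy <- lapply(1:10, function(i) mk(base + rnorm(150, 0, 0.5)))
  resid <- average_trials(noisy)$value - base
  expect_lt(abs(sd(resid) / (0.5 / sqrt(10)) - 1), 0.35)
  # heterogeneous lengths refuse to average
  expect_error(average_trials(list(one, photometry_trial(1:10, 10, s))),
               class = "needmot_alignment_error")
})
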