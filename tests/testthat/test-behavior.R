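test_that("raster validation and probability conversion behave", {
  expect_error(behavior_raster(list(c(0, 2, 1)), t_on = 0.1, t_off = 0.2),
               class = "needmot_input_error")
  expect_error(behavior_raster(list(c(0, 1), c(0, 1, 1)),
                               t_on = 0.05, t_off = 0.1),
               class = "needmot_input_error")

  r1 <- behavior_raster(list(rep(1, 50), rep(1, 50)), t_on = 1, t_off = 3)
  expect_true(all(raster_to_probability(r1, 10)$p == 1))

  # alternating bins smooth to 0.5 away from the edges
  alt <- behavior_raster(list(rep(c(0, 1), 25)), t_on = 1, t_off = 3)
  p <- raster_to_probability(alt, smooth_bins = 2)$p
  expect_true(all(abs(p[2:49] - 0.5) < 1e-9))

  # smoothing preserves the overall mean up to edge effects
  set.seed(11)
  rr <- behavior_raster(lapply(1:5, function(i) rbinom(100, 1, 0.4)),
                        t_on = 1, t_off = 5)
  raw_mean <- mean(colMeans(do.call(rbind, rr$trials)))
  sm_mean <- mean(raster_to_probability(rr, 10)$p)
  expect_lt(abs(raw_mean - sm_mean), 0.05)
})

test_that("the need behavior curve follows its three branches and clips", {
  tg <- seq(0.05, 30, by = 0.1)
  # no dynamics: constant baseline
  expect_true(all(need_behavior_model(tg, 5, 15, bn0 = 0.3, A = 0,
                                      leaky = 0) == 0.3))
  # steep ramp clips at the maintained threshold of 1
  v <- need_behavior_model(tg, 5, 15, bn0 = 0, A = 0.2, leaky = 0.05)
  expect_equal(max(v), 1)
  expect_equal(v[which.min(abs(tg - 14.95))], 1)  # 0.2 * 10 = 2, clipped
  # leak bound is enforced
  expect_error(need_behavior_model(tg, 5, 15, bn0 = 0, A = 0.1,
                                   leaky = 0.05),
               class = "needmot_parameter_error")
  # post-offset persistence: time above threshold after t_off + t_delay
  # equals (value_at_off - threshold) / leaky when unclipped
  bn0 <- 0; A <- 0.06; leaky <- 0.012; thr <- 0.3; t_delay <- 0.5
  tg2 <- seq(0.005, 80, by = 0.01)
  v2 <- need_behavior_model(tg2, 5, 15, bn0, A, leaky, t_delay)
  off_d <- 15 + t_delay
  v_off <- v2[which(tg2 >= off_d)[1]]  # decay-branch value at offset
  above <- tg2[v2 >= thr & tg2 >= off_d]
  expect_lt(abs((max(above) - off_d) - (v_off - thr) / leaky), 0.05)
  # gating: values below the generated-behavior threshold produce nothing
  vg <- need_behavior_model(tg, 5, 15, bn0 = 0.05, A = 0.06, leaky = 0.01,
                            gen_threshold = 0.2)
  expect_true(all(vg[vg > 0] >= 0.2))
})

test_that("the motivation behavior curve is a delayed boxcar", {
  tg <- seq(0.05, 30, by = 0.1)
  expect_true(all(motivation_behavior_model(tg, 5, 15, bm0 = 0.2,
                                            a_stim = 0) == 0.2))
  v <- motivation_behavior_model(tg, 5, 15, bm0 = 0, a_stim = 1,
                                 t_delay = 0.5)
  expect_true(all(v[tg >= 5.5 & tg < 15.5] == 1))
  expect_true(all(v[tg < 5.5 | tg >= 15.5] == 0))
  # boxcar area: integral of (model - bm0) = a_stim * (t_off - t_on)
  v2 <- motivation_behavior_model(tg, 5, 15, bm0 = 0.1, a_stim = 0.4,
                                  t_delay = 0)
  expect_lt(abs(sum(v2 - 0.1) * 0.1 - 0.4 * 10), 0.05)
})

test_that("behavior fits recover generating parameters", {
  # probability curve observed with additive noise
  tg <- seq(0.05, 30, by = 0.1)
  curve <- motivation_behavior_model(tg, 5, 15,
                                     bm0 = true_mot_behavior$bm0,
                                     a_stim = true_mot_behavior$a_stim,
                                     t_delay = true_mot_behavior$t_delay)
  set.seed(12)
  prob <- pmin(1, pmax(0, curve + rnorm(length(tg), 0, 0.05)))
  f <- fit_behavior(prob, 5, 15, "motivation", n_starts = 40, seed = 3,
                    t_grid = tg)
  expect_lt(abs(f$params[["a_stim"]] - true_mot_behavior$a_stim) /
              true_mot_behavior$a_stim, 0.1)
  expect_equal(f$k, 3)
})

test_that("behavior AIC dissociates the generating model", {
  gn <- generate_behavior_session("need", true_need_behavior,
                                  n_trials = 20, seed = 13)
  pn <- raster_to_probability(gn$raster, smooth_bins = 10)
  fn <- fit_behavior(pn, 5, 15, "need", n_starts = 10, seed = 3)
  fm <- fit_behavior(pn, 5, 15, "motivation", n_starts = 10, seed = 3)
  expect_lt(fn$aic, fm$aic)
  expect_equal(fn$k, 5)

  gm <- generate_behavior_session("motivation", true_mot_behavior,
                                  n_trials = 20, seed = 13)
  pm <- raster_to_probability(gm$raster, smooth_bins = 10)
  fn2 <- fit_behavior(pm, 5, 15, "need", n_starts = 10, seed = 3)
  fm2 <- fit_behavior(pm, 5, 15, "motivation", n_starts = 10, seed = 3)
  expect_lt(fm2$aic, fn2$aic)
})

test_that("model outputs always lie in [0, 1]", {
  tg <- seq(0.05, 30, by = 0.1)
  set.seed(14)
  for (i in 1:20) {
    A <- runif(1, 0, 1)
    v <- need_behavior_model(tg, 5, 15, bn0 = runif(1), A = A,
                             leaky = runif(1, 0, A / 4),
                             t_delay = runif(1, 0, 3))
    expect_true(all(v >= 0 & v <= 1))
    v2 <- motivation_behavior_model(tg, 5, 15, bm0 = runif(1),
                                    a_stim = runif(1),
                                    t_delay = runif(1, 0, 3))
    expect_true(all(v2 >= 0 & v2 <= 1))
  }
})
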