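test_that("sdd matches geometric-series arithmetic", {
  expect_equal(sdd(0, 0.99), 0)
  expect_equal(sdd(0.7, 0.99), 0.7)  # normalized infinite-horizon identity
  expect_equal(sdd(1, 0.99, horizon = 100, normalize = FALSE),
               (1 - 0.99^101) / 0.01)
  # finite-horizon closed forms agree with explicit summation
  k <- 0:50
  for (r in c(0, 0.002, -0.03)) {
    brute <- sum(0.9^k * pmax(0, 1 + r * k))
    expect_equal(sdd(1, 0.9, horizon = 50, normalize = FALSE, rate = r),
                 brute, tolerance = 1e-10)
  }
  expect_error(sdd(-1, 0.99), class = "needmot_input_error")
  expect_error(sdd(1, 1, horizon = Inf), class = "needmot_input_error")
})

test_that("compute_need applies the predicted-event weight", {
  p <- agent_params()
  expect_equal(compute_need(1, FALSE, p), 1)
  expect_equal(compute_need(1, TRUE, p), 0.9)
  expect_equal(compute_need(1, TRUE, agent_params(e = 1)), 0)
  expect_gte(compute_need(0.2, TRUE, agent_params(e = 3)), 0)  # floored
})

test_that("a zero threshold sends the agent straight to food", {
  p <- agent_params(threshold = 0)
  tr <- run_simulation("direct_need", "pred_changes_on_stop", "ID", p,
                       food_distance = 50, n_steps = 100, seed = 1)
  expect_equal(acquisition_time(tr), 50)
  tr2 <- run_simulation("accumulated_need", "pred_changes_on_stop", "ID",
                        p, food_distance = 50, n_steps = 100, seed = 1)
  expect_equal(acquisition_time(tr2), 50)
})

test_that("trajectories respect non-negativity and dwell-time holds", {
  for (policy in SIM_POLICIES) {
    tr <- run_simulation(policy, "pred_changes_on_stop", "ID",
                         n_steps = 2500, seed = 2)
    expect_true(all(tr$deficit >= 0))
    expect_true(all(tr$need >= 0))
    expect_true(all(tr$motivation >= 0))
    runs <- rle(tr$action)
    # every completed stop bout >= hold_stop, go bout >= hold_go
    if (length(runs$lengths) > 2) {
      inner <- seq(2, length(runs$lengths) - 1)
      stops <- runs$lengths[inner][runs$values[inner] == "stop"]
      gos <- runs$lengths[inner][runs$values[inner] == "go"]
      if (length(stops)) expect_true(all(stops >= 50))
      if (length(gos)) expect_true(all(gos >= 10))
    }
  }
})

test_that("stopping reactivates need for the direct agent (dithering)", {
  p <- agent_params()
  st <- list(t = 0L, deficit = 1, sdd_value = 0, predicted_change = 0,
             need = 0, motivation = 0, action = "go", position = 5L,
             phase = "accessible", since_switch = 100L)
  moving <- step_agent(st, p, "direct_need", "pred_changes_on_stop", "ID",
                       food_distance = 300)
  st_stop <- st; st_stop$action <- "stop"
  stopped <- step_agent(st_stop, p, "direct_need", "pred_changes_on_stop",
                        "ID", food_distance = 300)
  expect_lt(moving$need, p$threshold)   # projected relief while moving
  expect_gt(stopped$need, p$threshold)  # prediction reverts on stopping
  # below-threshold motivation keeps a stopped accumulated agent stopped
  acc <- step_agent(st_stop, p, "accumulated_need", "pred_changes_on_stop",
                    "ID", food_distance = 300)
  expect_equal(acc$action, "stop")
})

test_that("direct need delays acquisition relative to accumulated need", {
  d <- run_simulation("direct_need", "pred_changes_on_stop", "ID",
                      n_steps = 3000, seed = 3)
  a <- run_simulation("accumulated_need", "pred_changes_on_stop", "ID",
                      n_steps = 3000, seed = 3)
  expect_gt(acquisition_time(d), acquisition_time(a))
  expect_gt(n_go_bouts(d), 5)   # the direct agent dithers
  # the accumulated agent launches once and sustains a single bout
  expect_lte(n_go_bouts(a), 2)
})

test_that("the motion-independent prediction keeps the direct agent idle", {
  tr <- run_simulation("direct_need", "pred_independent", "ID",
                       n_steps = 1500, seed = 4)
  expect_true(is.na(acquisition_time(tr)))
  expect_true(all(tr$action == "stop"))
})

test_that("the inaccessible-start condition follows the staged schedule", {
  tr <- run_simulation("accumulated_need", "with_inaccessible", "ID",
                       n_steps = 6000, seed = 5)
  expect_true(all(tr$deficit[tr$t <= 100] == 0))
  expect_lt(max(abs(tr$deficit[101:600] - cumsum(rep(1 / 500, 500)))),
            1e-9)
  acq <- acquisition_time(tr)
  expect_false(is.na(acq))
  # tracked for 1000 steps after acquisition, then stops
  expect_equal(nrow(tr), acq + 1000)
  # eating brings the deficit down after acquisition
  expect_lt(min(tr$deficit[tr$t > acq]), tr$deficit[acq])
})

test_that("NID runs are reproducible and use the NID leak", {
  a1 <- run_simulation("accumulated_need", "pred_changes_on_stop", "NID",
                       n_steps = 500, seed = 6)
  a2 <- run_simulation("accumulated_need", "pred_changes_on_stop", "NID",
                       n_steps = 500, seed = 6)
  expect_identical(a1$deficit, a2$deficit)
  expect_identical(a1$motivation, a2$motivation)
  a3 <- run_simulation("accumulated_need", "pred_changes_on_stop", "NID",
                       n_steps = 500, seed = 7)
  expect_false(identical(a1$deficit, a3$deficit))
})

test_that("parameter sweeps summarize the grid deterministically", {
  single <- parameter_sweep(thresholds = 0.5, policies = "direct_need",
                            n_steps = 2000, seed = 8)
  expect_equal(nrow(single), 1)
  ref <- run_simulation("direct_need", "pred_changes_on_stop", "ID",
                        n_steps = 2000, seed = 8)
  expect_equal(single$acquisition_time, acquisition_time(ref))
  expect_equal(single$n_go_bouts, n_go_bouts(ref))

  # acquisition is non-decreasing in the threshold for the accumulated
  # policy (longer pre-accumulation), noise off
  sw <- parameter_sweep(thresholds = c(0.2, 0.4, 0.6),
                        policies = "accumulated_need", n_steps = 4000,
                        seed = 8)
  expect_true(all(diff(sw$acquisition_time) >= 0))

  # duplicate cells give identical rows
  dup <- parameter_sweep(thresholds = c(0.5, 0.5),
                         policies = "accumulated_need", n_steps = 2000,
                         seed = 8)
  expect_identical(dup[1, ], dup[2, ])
  expect_error(parameter_sweep(thresholds = numeric(), policies = "x"),
               class = "needmot_input_error")
})
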