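#' Default agent parameters for the foraging simulation
#'
#' Defaults follow the stated simulation settings: discount `gamma = 0.99`,
#' predicted-event weight `e = 0.1`, accumulation gain `a = 0.0015`,
#' motivation leak `0.001` per step (`0.0008` in the NID condition),
#' behavior threshold `0.5`, dwell-time holds of 50 steps after switching to
#' stop and 10 after switching to go, deficit increment `0.00001` per step,
#' and an eating-induced deficit decrease of `0.012` per step.
#'
#' @param gamma Discount factor in `(0, 1)`.
#' @param e Predicted-event weight (>= 0).
#' @param a Accumulation gain (>= 0).
#' @param leak Motivation decay per step (>= 0).
#' @param threshold Behavior-generation threshold.
#' @param hold_stop,hold_go Minimum dwell steps after switching to
#'   stop / go.
#' @param deficit_increment Deficit rise per step in the ID condition.
#' @param eat_rate Deficit decrease per step while eating.
#' @param horizon Projection horizon for the discounted-deficit sum
#'   (`Inf` uses the geometric limit).
#' @param nid_noise Half-width of the uniform per-step deficit noise in the
#'   NID condition.
#' @param nid_leak Leak used in the NID condition.
#' @return A named list of class `"agent_params"`.
#' @export
agent_params <- function(gamma = 0.99, e = 0.1, a = 0.0015, leak = 0.001,
                         threshold = 0.5, hold_stop = 50, hold_go = 10,
                         deficit_increment = 0.00001, eat_rate = 0.012,
                         horizon = Inf, nid_noise = 0.001,
                         nid_leak = 0.0008) {
  stopifnot(gamma > 0, gamma < 1, e >= 0, a >= 0, leak >= 0,
            hold_stop >= 0, hold_go >= 0, eat_rate > 0)
  structure(list(gamma = gamma, e = e, a = a, leak = leak,
                 threshold = threshold, hold_stop = hold_stop,
                 hold_go = hold_go, deficit_increment = deficit_increment,
                 eat_rate = eat_rate, horizon = horizon,
                 nid_noise = nid_noise, nid_leak = nid_leak),
            class = "agent_params")
}

#' Sum of discounted deficit
#'
#' Projects the homeostatic deficit forward and discounts it:
#' `SDD = sum_{k=0}^{horizon} gamma^k * max(0, deficit + rate * k)`.
#' With `rate = 0` this is the constant-deficit projection; a negative
#' `rate` models a predicted decrease of the deficit (e.g. imminent eating)
#' and a positive one a predicted increase. `normalize = TRUE` multiplies by
#' `(1 - gamma)` so that a constant deficit `d` maps to `d` at infinite
#' horizon, making SDD comparable to the behavior threshold.
#'
#' @param deficit Current deficit (>= 0).
#' @param gamma Discount factor.
#' @param horizon Number of projected steps (`Inf` allowed for
#'   `gamma < 1`).
#' @param normalize Multiply by `(1 - gamma)`?
#' @param rate Projected deficit change per step.
#' @return The (optionally normalized) discounted sum.
#' @examples
#' sdd(1, 0.99, horizon = 100, normalize = FALSE) # 63.7628...
#' sdd(1, 0.99)                                   # 1 (normalized, infinite)
#' @export
sdd <- function(deficit, gamma, horizon = Inf, normalize = TRUE, rate = 0) {
  if (deficit < 0) abort("`deficit` must be >= 0.",
                         class = "needmot_input_error")
  if (gamma >= 1 && is.infinite(horizon)) {
    abort("gamma >= 1 requires a finite horizon.",
          class = "needmot_input_error")
  }
  if (deficit == 0 && rate <= 0) return(0)
  K <- if (rate < 0) {
    min(horizon, ceiling(deficit / -rate) - 1)
  } else {
    horizon
  }
  if (is.infinite(K)) {
    s0 <- 1 / (1 - gamma)
    s1 <- gamma / (1 - gamma)^2
  } else {
    s0 <- (1 - gamma^(K + 1)) / (1 - gamma)
    s1 <- gamma * (1 - (K + 1) * gamma^K + K * gamma^(K + 1)) /
      (1 - gamma)^2
  }
  out <- deficit * s0 + rate * s1
  if (normalize) out * (1 - gamma) else out
}

#' Need from the discounted deficit and the predicted-event weight
#'
#' `need = max(0, SDD * (1 - e * prediction_active))`: an active predicted
#' gain compensates a fraction `e` of the discounted deficit. Need is never
#' negative.
#'
#' @param deficit Current deficit.
#' @param prediction_active Logical; is a predicted gain active?
#' @param params An [agent_params()].
#' @param projection_rate Deficit change per step assumed by the forward
#'   projection (see [sdd()]).
#' @return The need value (>= 0).
#' @examples
#' p <- agent_params()
#' compute_need(1, FALSE, p)           # 1
#' compute_need(1, TRUE, p)            # 0.9
#' compute_need(1, TRUE, agent_params(e = 1)) # 0
#' @export
compute_need <- function(deficit, prediction_active, params = agent_params(),
                         projection_rate = 0) {
  s <- sdd(deficit, params$gamma, horizon = params$horizon,
           normalize = TRUE, rate = projection_rate)
  max(0, s * (1 - params$e * as.numeric(prediction_active)))
}

#' Simulation conditions and policies
#' @format NULL
#' @export
SIM_CONDITIONS <- c("pred_changes_on_stop", "pred_independent",
                    "always_accessible", "with_inaccessible")

#' @rdname SIM_CONDITIONS
#' @format NULL
#' @export
SIM_POLICIES <- c("direct_need", "accumulated_need")

#' Advance the foraging agent by one step
#'
#' Implements one transition of the go/no-go agent. The deficit evolves per
#' the condition and deficit mode (linear rise schedule in
#' `with_inaccessible`; `+deficit_increment` per accessible step in ID;
#' constant plus seeded uniform noise in NID; `-eat_rate` while eating,
#' never below zero). Need is the e-weighted, normalized discounted deficit;
#' for the direct-need policy the forward projection is action dependent
#' under `pred_changes_on_stop` (moving agents project a decreasing deficit,
#' stopped agents an increasing one) and motion independent under
#' `pred_independent`. The accumulated-need policy integrates the
#' unpredicted need into motivation (`M <- max(0, M + a * need - leak)`)
#' from the moment food is accessible. Actions follow the policy's
#' threshold rule subject to the dwell-time holds; `go` advances the
#' position by one while food is accessible.
#'
#' @param state Named list: `t`, `deficit`, `need`, `motivation`, `action`
#'   (`"go"`/`"stop"`), `position`, `phase`, `since_switch`.
#' @param params An [agent_params()].
#' @param policy `"direct_need"` or `"accumulated_need"`.
#' @param condition One of `r paste0('"', SIM_CONDITIONS, '"', collapse = ", ")`.
#' @param deficit_mode `"ID"` (increasing deficit) or `"NID"`.
#' @param food_distance Steps to the food site.
#' @return The updated state list (with `sdd_value` and `predicted_change`
#'   fields for bookkeeping).
#' @export
step_agent <- function(state, params = agent_params(),
                       policy = c("direct_need", "accumulated_need"),
                       condition = SIM_CONDITIONS,
                       deficit_mode = c("ID", "NID"),
                       food_distance = 300) {
  policy <- match.arg(policy)
  condition <- match.arg(condition)
  deficit_mode <- match.arg(deficit_mode)
  leak <- if (deficit_mode == "NID") params$nid_leak else params$leak
  t <- state$t + 1L

  # --- environment: accessibility and deficit dynamics -------------------
  accessible <- if (condition == "with_inaccessible") t > 600 else TRUE
  eating <- accessible && state$position >= food_distance &&
    state$action == "go"
  d <- state$deficit
  if (condition == "with_inaccessible" && t <= 600) {
    d <- if (t <= 100) 0 else min(1, d + 1 / 500)
  } else if (eating) {
    d <- max(0, d - params$eat_rate)
  } else if (deficit_mode == "ID") {
    d <- d + params$deficit_increment
  } else {
    d <- max(0, d + runif(1, -params$nid_noise, params$nid_noise))
  }

  # --- prediction and need ----------------------------------------------
  if (policy == "direct_need") {
    active <- switch(condition,
      pred_independent = accessible,
      accessible && (state$action == "go"))
    proj <- if (active) -params$eat_rate else params$deficit_increment
  } else {
    # the motivation agent's prediction enters through accumulation onset
    # at accessibility, not through the momentary need signal
    active <- FALSE
    proj <- params$deficit_increment
  }
  s <- sdd(d, params$gamma, horizon = params$horizon, normalize = TRUE,
           rate = proj)
  need <- max(0, s * (1 - params$e * as.numeric(active)))
  motivation <- if (accessible) {
    max(0, state$motivation + params$a * need - leak)
  } else {
    state$motivation
  }

  # --- action selection under dwell-time holds --------------------------
  drive <- if (policy == "direct_need") need else motivation
  desired <- if (drive > params$threshold) "go" else "stop"
  action <- state$action
  since <- state$since_switch + 1L
  hold <- if (action == "stop") params$hold_stop else params$hold_go
  if (desired != action && since >= hold) {
    action <- desired
    since <- 0L
  }
  position <- state$position
  if (action == "go" && accessible && position < food_distance) {
    position <- position + 1L
  }
  phase <- if (!accessible) "inaccessible"
    else if (eating || (position >= food_distance)) "eating" else "accessible"

  list(t = t, deficit = d, sdd_value = s,
       predicted_change = need - s, need = need, motivation = motivation,
       action = action, position = position, phase = phase,
       since_switch = since)
}

#' Run a full foraging simulation
#'
#' Steps the agent for `n_steps` (in the `with_inaccessible` condition the
#' run continues for 1000 steps after food is first consumed, to show the
#' post-consumption dynamics). The trajectory records deficit, discounted
#' deficit, predicted change, need, motivation, action, position and phase
#' at every step; the acquisition time is the first step at which the
#' position reaches the food while it is accessible.
#'
#' @inheritParams step_agent
#' @param n_steps Maximum number of steps.
#' @param seed Integer seed (used by the NID deficit noise).
#' @param initial_deficit Starting deficit; defaults to 1 in the
#'   always-accessible conditions and 0 in `with_inaccessible`.
#' @return A tibble of class `"agent_trajectory"`, one row per step, with
#'   attributes `acquisition_time` (step index or `NA`), `policy`,
#'   `condition`, `deficit_mode` and `params`.
#' @export
run_simulation <- function(policy = c("direct_need", "accumulated_need"),
                           condition = SIM_CONDITIONS,
                           deficit_mode = c("ID", "NID"),
                           params = agent_params(), food_distance = 300,
                           n_steps = 5000, seed = 1,
                           initial_deficit = NULL) {
  policy <- match.arg(policy)
  condition <- match.arg(condition)
  deficit_mode <- match.arg(deficit_mode)
  stopifnot(n_steps >= 1)
  set.seed(seed)
  d0 <- initial_deficit %||%
    (if (condition == "with_inaccessible") 0 else 1)
  state <- list(t = 0L, deficit = d0, sdd_value = 0, predicted_change = 0,
                need = 0, motivation = 0, action = "stop",
                position = 0L, phase = "accessible",
                since_switch = 10000L)
  cols <- c("deficit", "sdd_value", "predicted_change", "need", "motivation",
            "position")
  rec <- lapply(setNames(cols, cols), function(x) numeric(n_steps))
  act <- character(n_steps)
  ph <- character(n_steps)
  acquisition <- NA_integer_
  t_stop <- n_steps
  i <- 0L
  while (i < t_stop) {
    i <- i + 1L
    state <- step_agent(state, params, policy, condition, deficit_mode,
                        food_distance)
    for (nm in cols) rec[[nm]][i] <- state[[nm]]
    act[i] <- state$action
    ph[i] <- state$phase
    if (is.na(acquisition) && state$position >= food_distance) {
      acquisition <- i
      if (condition == "with_inaccessible") {
        t_stop <- min(n_steps, i + 1000L)
      }
    }
  }
  out <- tibble(t = seq_len(i), deficit = rec$deficit[1:i],
                sdd = rec$sdd_value[1:i],
                predicted_change = rec$predicted_change[1:i],
                need = rec$need[1:i], motivation = rec$motivation[1:i],
                action = act[1:i], position = rec$position[1:i],
                phase = ph[1:i])
  structure(out, acquisition_time = acquisition, policy = policy,
            condition = condition, deficit_mode = deficit_mode,
            params = params, food_distance = food_distance, seed = seed,
            class = c("agent_trajectory", class(out)))
}

#' @rdname run_simulation
#' @param trajectory An `"agent_trajectory"`.
#' @export
acquisition_time <- function(trajectory) attr(trajectory, "acquisition_time")

#' Count go bouts of a trajectory
#' @inheritParams acquisition_time
#' @return Number of maximal runs of consecutive `go` actions.
#' @export
n_go_bouts <- function(trajectory) {
  r <- rle(trajectory$action)
  sum(r$values == "go")
}

#' Parameter sweep over the foraging simulation
#'
#' Crosses thresholds, accumulation gains and discount factors (the stated
#' robustness ranges are threshold and `a` in `[0.1, 1]` and `gamma` in
#' `[0.9, 1)`) with policies and conditions, running one deterministic
#' simulation per cell.
#'
#' @param thresholds,a_values,gammas Numeric grids.
#' @param policies,conditions Character vectors of policies / conditions.
#' @param deficit_mode `"ID"` or `"NID"`.
#' @param params Base [agent_params()]; swept values override it cell-wise.
#' @param food_distance,n_steps,seed As in [run_simulation()].
#' @return A tibble, one row per grid cell, with `acquisition_time`,
#'   `n_go_bouts` and `total_go_steps`.
#' @export
parameter_sweep <- function(thresholds = 0.5, a_values = 0.0015,
                            gammas = 0.99, policies = SIM_POLICIES,
                            conditions = "pred_changes_on_stop",
                            deficit_mode = "ID", params = agent_params(),
                            food_distance = 300, n_steps = 5000, seed = 1) {
  grid <- expand.grid(threshold = thresholds, a = a_values, gamma = gammas,
                      policy = policies, condition = conditions,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) {
    abort("Empty sweep grid.", class = "needmot_input_error")
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- params
    p$threshold <- g$threshold; p$a <- g$a; p$gamma <- g$gamma
    tr <- run_simulation(g$policy, g$condition, deficit_mode, p,
                         food_distance, n_steps, seed)
    tibble(threshold = g$threshold, a = g$a, gamma = g$gamma,
           policy = g$policy, condition = g$condition,
           acquisition_time = acquisition_time(tr) %||% NA_integer_,
           n_go_bouts = n_go_bouts(tr),
           total_go_steps = sum(tr$action == "go"))
  })
  dplyr::bind_rows(res)
}
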