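# shared fixtures: a 20-Hz kernel and canonical true parameter sets

kernel20 <- gcamp_kernel(rate = 20)

true_need_params <- list(n0 = 1, steps = c(0.8, 0.7, 0.9, -1.2),
                         offset = 0.2)
true_mot_params <- list(n0 = 1, m0 = 0, a = 0.35, leak = 0.15,
                        steps = c(0.25, 0.25, 0.3, 0), offset = 0.2)

true_need_behavior <- list(bn0 = 0.05, A = 0.08, leaky = 0.02,
                           t_delay = 1, gen_threshold = 0.1)
true_mot_behavior <- list(bm0 = 0.05, a_stim = 0.85, t_delay = 0.5)

# fit all four candidate latent models to an averaged multi-test trial
fit_candidates <- function(avg, test_id = "multi_gain_loss",
                           models = MODEL_NAMES, n_starts = 3, seed = 7) {
  rate <- trial_rate(avg)
  lapply(setNames(models, models), function(m) {
    spec <- latent_model_spec(test_id, m, trial_schedule(avg), kernel20,
                              rate = rate, mode = "crop_last5s")
    fit_model(avg, spec, n_starts = n_starts, seed = seed)
  })
}

# average of a freshly generated synthetic session
make_avg_session <- function(generating_model, true_params, seed,
                             n_trials = 8, noise_sd = 0.3,
                             event_jitter_sd = 0.3, zscore = TRUE,
                             true_delay_s = 0,
                             test_id = "multi_gain_loss") {
  sp <- session_spec(test_id, n_trials, generating_model, true_params,
                     event_jitter_sd = event_jitter_sd,
                     noise_sd = noise_sd, rate = 20, kernel = kernel20,
                     zscore = zscore, true_delay_s = true_delay_s,
                     seed = seed)
  average_trials(generate_photometry_session(sp)$trials)
}

# forward-Euler oracle for the leaky accumulation of a stepwise need
# (left-Riemann sums are exact for piecewise-constant integrands when all
# breakpoints lie on the dt grid)
euler_motivation <- function(schedule, n0, steps, m0, a, leak,
                             dt = 0.001, rate = 100) {
  w <- schedule_window(schedule)
  acc <- schedule$time_s[schedule$kind == "accessibility"]
  if (length(acc) == 0) {
    n_out <- round((w[2] - w[1]) * rate)
    return(rep(m0, n_out))
  }
  t0 <- acc[1]
  ce <- schedule$time_s[schedule$kind == "consumption_end"]
  t_ce <- if (length(ce) > 0) ce[1] else w[2]
  abn <- schedule$time_s[schedule$kind == "abandon"]
  t_abn <- if (length(abn) > 0) abn[1] else Inf
  sev <- step_events(schedule)
  tj <- seq(w[1], w[2], by = dt)
  N <- rep(n0, length(tj))
  for (i in seq_len(nrow(sev))) {
    N[tj >= sev$time_s[i]] <- N[tj >= sev$time_s[i]] - steps[i]
  }
  N[tj >= t_abn] <- n0
  dM <- (a * N * (tj >= t0 & tj < t_ce) - leak * (tj >= t0)) * dt
  M <- m0 + c(0, cumsum(dM[-length(dM)]))
  M[tj >= t_abn - 1e-12] <- m0
  t_out <- w[1] + (seq_len(round((w[2] - w[1]) * rate)) - 1) / rate
  M[round((t_out - w[1]) / dt) + 1]
}

# random ms-aligned event schedules with <= 10 events
random_schedule <- function(seed, max_events = 10) {
  set.seed(seed)
  n_ev <- sample(2:max_events, 1)
  repeat {
    times <- sort(round(runif(n_ev, 0.5, 11.5), 3))
    if (all(diff(times) > 0.2)) break
  }
  kinds <- c("accessibility",
             sample(c("gain", "loss"), n_ev - 1, replace = TRUE))
  if (n_ev >= 4 && runif(1) < 0.5) kinds[n_ev] <- "consumption_end"
  event_schedule(data.frame(time_s = times,
                            label = paste0("ev", seq_len(n_ev)),
                            kind = kinds),
                 window = c(0, 12))
}

random_need_steps <- function(schedule, seed) {
  set.seed(seed + 5000)
  sev <- step_events(schedule)
  mag <- runif(nrow(sev), 0.1, 1)
  ifelse(sev$kind == "gain", mag, -mag)
}
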