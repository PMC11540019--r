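#' Template event schedules for the behavioral tests
#'
#' Encodes the trial structure of each test: single predicted-gain tests
#' (seeking initiation / food contact preceded by an accessibility moment),
#' the single predicted-loss test (inaccessibility only), abandon tests
#' (gain followed by voluntary eating abandon, which resets the latents to
#' baseline), and the multi-event tests with a 10-s initial inaccessibility
#' before the accessibility moment and a gain cascade (seeking, proximity,
#' contact), plus consumption end and a final inaccessibility in
#' `multi_gain_loss`.
#'
#' @param test_id One of `r paste0('"', TEST_IDS, '"', collapse = ", ")`.
#' @return An [event_schedule()].
#' @export
template_schedule <- function(test_id) {
  test_id <- match.arg(test_id, TEST_IDS)
  ev <- switch(test_id,
    gain1 = data.frame(
      time_s = c(2, 5), label = c("accessibility", "seeking_initiation"),
      kind = c("accessibility", "gain")),
    gain2 = data.frame(
      time_s = c(2, 5), label = c("accessibility", "contact"),
      kind = c("accessibility", "gain")),
    loss1 = data.frame(
      time_s = 5, label = "inaccessibility", kind = "loss"),
    loss2 = data.frame(
      time_s = c(2, 5, 10), label = c("accessibility", "rearing", "abandon"),
      kind = c("accessibility", "gain", "abandon")),
    loss3 = data.frame(
      time_s = c(2, 5, 10),
      label = c("food_cue", "seeking_initiation", "abandon"),
      kind = c("accessibility", "gain", "abandon")),
    multi_gain = data.frame(
      time_s = c(10, 13, 16, 19),
      label = c("accessibility", "seeking_initiation", "proximate_to_food",
                "food_contact"),
      kind = c("accessibility", "gain", "gain", "gain")),
    multi_gain_loss = data.frame(
      time_s = c(10, 13, 16, 19, 22, 31),
      label = c("accessibility", "seeking_initiation", "proximate_to_food",
                "food_contact", "consumption_end", "inaccessibility"),
      kind = c("accessibility", "gain", "gain", "gain", "consumption_end",
               "loss")))
  window <- switch(test_id,
    gain1 = , gain2 = , loss1 = c(0, 15),
    loss2 = , loss3 = c(0, 20),
    multi_gain = c(0, 30),
    multi_gain_loss = c(0, 40))
  event_schedule(ev, window)
}

#' Generate per-trial event schedules with timing jitter
#'
#' Event timing varies greatly across self-paced trials; the generator
#' perturbs the template times with truncated Gaussian jitter (the
#' accessibility moment is experimenter-scheduled and kept fixed) and
#' resamples any draw that violates ordering, a 0.5-s minimum gap, or the
#' trial window.
#'
#' @param test_id One of `r paste0('"', TEST_IDS, '"', collapse = ", ")`.
#' @param n_trials Number of schedules.
#' @param jitter_sd Gaussian jitter SD in seconds (0 reproduces the
#'   template).
#' @param seed Integer seed.
#' @return A list of [event_schedule()] objects.
#' @export
generate_schedule <- function(test_id, n_trials, jitter_sd = 0.3, seed = 1) {
  template <- template_schedule(test_id)
  w <- schedule_window(template)
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    repeat {
      t_new <- template$time_s +
        ifelse(template$kind == "accessibility", 0,
               rnorm(nrow(template), 0, jitter_sd))
      ok <- all(diff(t_new) >= 0.5) &&
        all(t_new > w[1] + 0.1) && all(t_new < w[2] - 0.1)
      if (ok || jitter_sd == 0) break
    }
    event_schedule(data.frame(time_s = t_new, label = template$label,
                              kind = template$kind), w)
  })
}

#' Specification of a synthetic photometry session
#'
#' Bundles everything needed to simulate a session: the test, the
#' generating latent model and its true parameters, event jitter, additive
#' noise in z-units, the calcium kernel and the sampling rate.
#'
#' @param test_id One of `r paste0('"', TEST_IDS, '"', collapse = ", ")`.
#' @param n_trials Trials per session (>= 1).
#' @param generating_model One of
#'   `r paste0('"', MODEL_NAMES, '"', collapse = ", ")`.
#' @param true_params Named list passed to [build_test_model()] (plus an
#'   optional `offset`).
#' @param event_jitter_sd Per-trial event jitter SD, seconds.
#' @param noise_sd Additive Gaussian noise SD, z-units.
#' @param rate Samples per second.
#' @param kernel Kernel vector (default [gcamp_kernel()] at `rate`).
#' @param conv_mode Boundary handling used when generating
#'   (`"pad_mean"` for the single-event tests, `"none"` for the multi
#'   tests whose fits crop the first 5 s instead).
#' @param true_delay_s True consumption-end delay baked into the latent
#'   (multi_gain_loss only); the recorded schedules keep the nominal time,
#'   mimicking observer mislabeling.
#' @param zscore Z-score each trial (as the preprocessing pipeline would)?
#' @param ar1 AR(1) coefficient for temporally correlated noise (0 = iid).
#' @param seed Integer seed.
#' @return A list of class `"session_spec"`.
#' @export
session_spec <- function(test_id, n_trials, generating_model, true_params,
                         event_jitter_sd = 0.3, noise_sd = 0.3, rate = 20,
                         kernel = NULL, conv_mode = NULL, true_delay_s = 0,
                         zscore = TRUE, ar1 = 0, seed = 1) {
  test_id <- match.arg(test_id, TEST_IDS)
  generating_model <- match.arg(generating_model, MODEL_NAMES)
  stopifnot(n_trials >= 1, noise_sd >= 0)
  kernel <- kernel %||% gcamp_kernel(rate = rate)
  conv_mode <- conv_mode %||%
    (if (test_id %in% c("multi_gain", "multi_gain_loss")) "none"
     else "pad_mean")
  structure(list(test_id = test_id, n_trials = n_trials,
                 generating_model = generating_model,
                 true_params = true_params,
                 event_jitter_sd = event_jitter_sd, noise_sd = noise_sd,
                 rate = rate, kernel = kernel, conv_mode = conv_mode,
                 true_delay_s = true_delay_s, zscore = zscore, ar1 = ar1,
                 seed = seed),
            class = "session_spec")
}

ar1_noise <- function(n, sd, phi) {
  if (phi == 0) return(rnorm(n, 0, sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

#' Generate a ground-truth-labeled synthetic photometry session
#'
#' For each trial: draw a jittered schedule, build the true latent
#' ([build_test_model()]), convolve it with the calcium kernel
#' ([predict_signal()]), add noise, and optionally z-score. The returned
#' ground-truth bundle carries the true latents, schedules and parameters
#' so fitting can be validated in closed loop.
#'
#' @param spec A [session_spec()].
#' @return A list: `trials` (list of [photometry_trial()]), `truth`
#'   (list with `latents`, `schedules`, `params`, `model`, `delay_s`).
#' @export
generate_photometry_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  schedules <- generate_schedule(spec$test_id, spec$n_trials,
                                 spec$event_jitter_sd, spec$seed)
  set.seed(spec$seed + 1000L)
  latents <- vector("list", spec$n_trials)
  trials <- vector("list", spec$n_trials)
  for (i in seq_len(spec$n_trials)) {
    latents[[i]] <- build_test_model(spec$test_id, schedules[[i]],
                                     spec$generating_model,
                                     spec$true_params, rate = spec$rate,
                                     delay_s = spec$true_delay_s)
    clean <- predict_signal(latents[[i]], spec$kernel,
                            offset = spec$true_params$offset %||% 0,
                            mode = spec$conv_mode)
    v <- clean + ar1_noise(length(clean), spec$noise_sd, spec$ar1)
    if (spec$zscore) v <- zscore(v)
    trials[[i]] <- photometry_trial(v, rate = spec$rate,
                                    schedule = schedules[[i]],
                                    zscored = spec$zscore)
  }
  list(trials = trials,
       truth = list(latents = latents, schedules = schedules,
                    params = spec$true_params,
                    model = spec$generating_model,
                    delay_s = spec$true_delay_s))
}

#' Generate a synthetic behavior raster from a probability model
#'
#' Draws each bin as an independent Bernoulli sample of the generating
#' curve (Eq.-3-type need dynamics with post-offset persistence, or
#' Eq.-4-type motivation dynamics with immediate cessation).
#'
#' @param model `"need"` or `"motivation"`.
#' @param params Named list. Need: `bn0`, `A`, `leaky`, `t_delay`,
#'   optionally `gen_threshold`. Motivation: `bm0`, `a_stim`, `t_delay`.
#' @param n_trials Number of raster trials.
#' @param t_on,t_off Stimulation window, seconds.
#' @param duration_s Trial length, seconds.
#' @param bin_s Bin width (default 0.1 s = 10 bins/s).
#' @param seed Integer seed.
#' @return A list: `raster` ([behavior_raster()]) and `truth` (the
#'   generating curve and parameters).
#' @export
generate_behavior_session <- function(model = c("need", "motivation"),
                                      params, n_trials, t_on = 5,
                                      t_off = 15, duration_s = 30,
                                      bin_s = 0.1, seed = 1) {
  model <- match.arg(model)
  n_bins <- round(duration_s / bin_s)
  t_grid <- (seq_len(n_bins) - 0.5) * bin_s
  curve <- if (model == "need") {
    need_behavior_model(t_grid, t_on, t_off, bn0 = params$bn0,
                        A = params$A, leaky = params$leaky,
                        t_delay = params$t_delay %||% 0,
                        gen_threshold = params$gen_threshold)
  } else {
    motivation_behavior_model(t_grid, t_on, t_off, bm0 = params$bm0,
                              a_stim = params$a_stim,
                              t_delay = params$t_delay %||% 0)
  }
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    as.numeric(runif(n_bins) < curve)
  })
  list(raster = behavior_raster(trials, bin_s = bin_s, t_on = t_on,
                                t_off = t_off),
       truth = list(curve = curve, t_grid = t_grid, params = params,
                    model = model))
}
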