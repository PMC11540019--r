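#' Behavior rasters
#'
#' A raster holds one binary series per trial: each 1-s period is divided
#' into bins (default 0.1 s, i.e. 10 bins/s) and a bin is 1 whenever the
#' behavior occurred during it. Stimulation on/off times are carried as
#' metadata.
#'
#' @param trials List of equal-length binary (0/1) vectors.
#' @param bin_s Bin width in seconds (default 0.1).
#' @param t_on,t_off Stimulation onset/offset in seconds from trial start.
#' @return A list of class `"behavior_raster"`.
#' @export
behavior_raster <- function(trials, bin_s = 0.1, t_on, t_off) {
  if (length(trials) < 1) {
    abort("Raster needs at least one trial.", class = "needmot_input_error")
  }
  lens <- vapply(trials, length, integer(1))
  if (length(unique(lens)) != 1) {
    abort("All raster trials must have equal length.",
          class = "needmot_input_error")
  }
  ok <- vapply(trials, function(x) all(x %in% c(0, 1)), logical(1))
  if (!all(ok)) {
    abort("Raster bins must be 0 or 1.", class = "needmot_input_error")
  }
  n_bins <- lens[1]
  if (!(t_on < t_off) || t_off > n_bins * bin_s) {
    abort("Need t_on < t_off within the trial window.",
          class = "needmot_input_error")
  }
  structure(list(trials = trials, bin_s = bin_s, t_on = t_on, t_off = t_off,
                 n_bins = n_bins),
            class = "behavior_raster")
}

#' @rdname behavior_raster
#' @param raster A behavior raster.
#' @export
raster_times <- function(raster) {
  (seq_len(raster$n_bins) - 0.5) * raster$bin_s
}

moving_average <- function(x, width) {
  # centered moving average (even widths lean one bin forward) with
  # shrinking windows at the edges
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - floor((width - 1) / 2))
    hi <- min(n, i + ceiling((width - 1) / 2))
    mean(x[lo:hi])
  }, numeric(1))
}

#' Convert a raster to a smoothed behavior probability curve
#'
#' Per-bin mean across trials, normalized into `[0, 1]` (a no-op for
#' well-formed 0/1 rasters), then a centered moving average of
#' `smooth_bins` bins (10 bins for a 10-s stimulus test, 60 otherwise)
#' with shrinking windows at the edges.
#'
#' @param raster A [behavior_raster()].
#' @param smooth_bins Moving-average width in bins (>= 1).
#' @return A tibble with columns `time_s` and `p`.
#' @export
raster_to_probability <- function(raster, smooth_bins = 10) {
  if (smooth_bins < 1) {
    abort("`smooth_bins` must be >= 1.", class = "needmot_input_error")
  }
  m <- do.call(rbind, raster$trials)
  p <- colMeans(m)
  if (max(p) > 1) p <- p / max(p)
  tibble(time_s = raster_times(raster),
         p = moving_average(p, smooth_bins))
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Need-model behavior probability curve
#'
#' Upon activation of need-encoding neurons at `t_on`, need jumps and its
#' leaky accumulation (the motivation level driving behavior) ramps up with
#' slope `A` until `t_off`, then decays through the remaining leak:
#' \deqn{BN(t) = BN0                       \quad (t < t_{on} + t_{delay})}
#' \deqn{BN(t) = BN0 + A (t - t_{on})      \quad (t_{on}+t_{delay} \le t < t_{off}+t_{delay})}
#' \deqn{BN(t) = BN0 + A (t_{off} - t_{on}) - Leaky (t - t_{on}) \quad (t \ge t_{off}+t_{delay})}
#' clipped into `[0, 1]` (the maintained-behavior threshold is 1). The decay
#' is anchored at `t_on` as printed in the model definition;
#' `anchor = "offset"` selects a continuity-preserving variant anchored at
#' `t_off`. The leak may not exceed a quarter of the rise slope
#' (`leaky <= A / 4`). If `gen_threshold` is given, the curve is gated:
#' values below the generated-behavior threshold produce no behavior
#' (probability 0).
#'
#' @param t_grid Bin-center times, seconds.
#' @param t_on,t_off Stimulation window, seconds.
#' @param bn0 Baseline probability in `[0, 1]`.
#' @param A Ramp slope per second (>= 0).
#' @param leaky Decay rate per second (0 <= `leaky` <= `A / 4`).
#' @param t_delay Neural-to-behavior delay, seconds (>= 0).
#' @param gen_threshold Optional generated-behavior threshold in `[0, 1]`.
#' @param anchor `"onset"` (as printed) or `"offset"` (continuous variant).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
need_behavior_model <- function(t_grid, t_on, t_off, bn0, A, leaky,
                                t_delay = 0, gen_threshold = NULL,
                                anchor = c("onset", "offset")) {
  anchor <- match.arg(anchor)
  if (!(t_on < t_off)) {
    abort("Need t_on < t_off.", class = "needmot_input_error")
  }
  if (leaky > A / 4 + 1e-12) {
    abort("Leak may not exceed a quarter of the rise slope (leaky <= A/4).",
          class = "needmot_parameter_error")
  }
  on_d <- t_on + t_delay
  off_d <- t_off + t_delay
  ramp_top <- bn0 + A * (t_off - t_on)
  v <- ifelse(t_grid < on_d, bn0,
         ifelse(t_grid < off_d, bn0 + A * (t_grid - t_on),
           if (anchor == "onset") {
             ramp_top - leaky * (t_grid - t_on)
           } else {
             ramp_top - leaky * (t_grid - off_d)
           }))
  v <- clip01(v)
  if (!is.null(gen_threshold)) v[v < gen_threshold] <- 0
  v
}

#' Motivation-model behavior probability curve
#'
#' Motivation (and the behavior it drives) steps up by `a_stim` over the
#' delayed stimulation window and returns to baseline immediately at offset:
#' a boxcar on `[t_on + t_delay, t_off + t_delay)`, clipped into `[0, 1]`.
#'
#' @inheritParams need_behavior_model
#' @param bm0 Baseline probability in `[0, 1]`.
#' @param a_stim Stimulus-evoked step (>= 0).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
motivation_behavior_model <- function(t_grid, t_on, t_off, bm0, a_stim,
                                      t_delay = 0) {
  if (!(t_on < t_off)) {
    abort("Need t_on < t_off.", class = "needmot_input_error")
  }
  on_d <- t_on + t_delay
  off_d <- t_off + t_delay
  clip01(ifelse(t_grid >= on_d & t_grid < off_d, bm0 + a_stim, bm0))
}

#' Fit a behavior-probability model to a smoothed curve
#'
#' Multi-start bounded fit of the need (k = 5: `bn0`, `A`, `leaky`,
#' `t_delay`, `gen_threshold`) or motivation (k = 3: `bm0`, `a_stim`,
#' `t_delay`) behavior model by RMSE, with all probability-scale parameters
#' bounded in `[0, 1]`; slopes are bounded in `[0, 1]` per second and the
#' delay in `[0, 5]` s. AIC uses the same `N ln(RSS/N) + 2K` form as the
#' neural fits. The need model's leak bound `leaky <= A / 4` is enforced by
#' reparameterizing `leaky = leak_frac * A / 4` with `leak_frac` in `[0, 1]`.
#'
#' @param prob A tibble from [raster_to_probability()] (columns `time_s`,
#'   `p`), or a numeric vector with `t_grid` supplied.
#' @param t_on,t_off Stimulation window, seconds.
#' @param model `"need"` or `"motivation"`.
#' @param n_starts,seed,maxit Optimizer settings.
#' @param t_grid Bin times when `prob` is a bare numeric vector.
#' @param anchor Decay anchor for the need model.
#' @return A `"needmot_fit"`.
#' @export
fit_behavior <- function(prob, t_on, t_off, model = c("need", "motivation"),
                         n_starts = 20, seed = 1, maxit = 200,
                         t_grid = NULL, anchor = "onset") {
  model <- match.arg(model)
  if (is.data.frame(prob)) {
    t_grid <- prob$time_s
    y <- prob$p
  } else {
    y <- prob
    if (is.null(t_grid)) {
      abort("Supply `t_grid` when `prob` is a bare vector.",
            class = "needmot_input_error")
    }
  }
  if (any(y < 0 | y > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "needmot_input_error")
  }
  spec <- if (model == "need") {
    model_spec(
      name = "need",
      predict = function(par) {
        need_behavior_model(t_grid, t_on, t_off, bn0 = par[["bn0"]],
                            A = par[["A"]],
                            leaky = par[["leak_frac"]] * par[["A"]] / 4,
                            t_delay = par[["t_delay"]],
                            gen_threshold = par[["gen_threshold"]],
                            anchor = anchor)
      },
      lower = c(bn0 = 0, A = 0, leak_frac = 0, t_delay = 0,
                gen_threshold = 0),
      upper = c(bn0 = 1, A = 1, leak_frac = 1, t_delay = 5,
                gen_threshold = 1))
  } else {
    model_spec(
      name = "motivation",
      predict = function(par) {
        motivation_behavior_model(t_grid, t_on, t_off, bm0 = par[["bm0"]],
                                  a_stim = par[["a_stim"]],
                                  t_delay = par[["t_delay"]])
      },
      lower = c(bm0 = 0, a_stim = 0, t_delay = 0),
      upper = c(bm0 = 1, a_stim = 1, t_delay = 5))
  }
  fit_model(y, spec, n_starts = n_starts, seed = seed, maxit = maxit)
}
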