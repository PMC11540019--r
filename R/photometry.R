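#' GCaMP6s single-pulse response kernel
#'
#' Latent variables are convolved with a calcium-indicator kernel before
#' comparison to fiber-photometry data, to account for the slow dynamics of
#' GCaMP6s. The kernel is a double exponential
#' `k(t) = c * (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)` on
#' `[0, duration]`, with `c` chosen so the peak equals `peak_amplitude`.
#' Defaults follow published GCaMP6s kinetics (rise ~0.2 s, decay ~2.6 s).
#'
#' @param tau_rise Rise time constant, seconds (> 0).
#' @param tau_decay Decay time constant, seconds (> `tau_rise`).
#' @param duration Kernel support, seconds.
#' @param rate Samples per second.
#' @param peak_amplitude Peak value of the kernel (> 0).
#' @return Numeric vector of length `round(duration * rate)` with attributes
#'   `rate` and `spec`.
#' @examples
#' k <- gcamp_kernel(rate = 100)
#' which.max(k) / 100  # peak near tau_rise * log(1 + tau_decay / tau_rise)
#' @export
gcamp_kernel <- function(tau_rise = 0.2, tau_decay = 2.6, duration = 10,
                         rate = 100, peak_amplitude = 1) {
  if (tau_rise <= 0 || tau_decay <= tau_rise) {
    abort("Need 0 < tau_rise < tau_decay.", class = "needmot_kernel_error")
  }
  if (peak_amplitude <= 0) {
    abort("`peak_amplitude` must be positive.", class = "needmot_kernel_error")
  }
  t <- (seq_len(round(duration * rate)) - 1) / rate
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  # analytic peak of the double exponential
  t_pk <- tau_rise * log(1 + tau_decay / tau_rise)
  k_pk <- (1 - exp(-t_pk / tau_rise)) * exp(-t_pk / tau_decay)
  k <- k * (peak_amplitude / k_pk)
  structure(k, rate = rate,
            spec = list(tau_rise = tau_rise, tau_decay = tau_decay,
                        duration = duration, rate = rate,
                        peak_amplitude = peak_amplitude))
}

# causal discrete convolution, FFT-based; y[i] = sum_j k[j] x[i-j+1]
causal_convolve <- function(x, k) {
  n <- length(x)
  m <- length(k)
  N <- stats::nextn(n + m - 1, 2)
  xf <- stats::fft(c(x, numeric(N - n)))
  kf <- stats::fft(c(k, numeric(N - m)))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / N
}

#' Predict a photometry signal from a latent trace
#'
#' Convolves the latent with the calcium kernel and adds a free offset (the
#' offset absorbs baseline fluorescence and the negative values that
#' z-scoring introduces). Convolution with a causal kernel produces a sharp
#' onset artifact at the start of the trace, handled by `mode`:
#' `"pad_mean"` prepends 1.25 s of samples equal to the mean of the first
#' 0.5 s of the latent before convolving (125 and 50 samples at 100 Hz);
#' `"crop_last5s"` drops the first 5 s of the trace after convolving, so
#' that only the last 5 s of a 10-s initial inaccessibility segment enter
#' the fit; `"none"` applies no boundary handling.
#'
#' @param latent A [latent_trace()] sampled at the kernel rate.
#' @param kernel A kernel from [gcamp_kernel()] (or any numeric vector at
#'   the latent's rate).
#' @param offset Additive offset applied after convolution.
#' @param mode Boundary handling, see Details.
#' @return Numeric vector; for `"crop_last5s"` it is shorter than the
#'   latent by `5 * rate` samples.
#' @export
predict_signal <- function(latent, kernel, offset = 0,
                           mode = c("pad_mean", "crop_last5s", "none")) {
  mode <- match.arg(mode)
  v <- trace_values(latent)
  rate <- trace_rate(latent)
  if (length(v) < length(kernel)) {
    abort("Latent trace is shorter than the kernel.",
          class = "needmot_window_error")
  }
  if (mode == "pad_mean") {
    n_pad <- round(1.25 * rate)
    n_avg <- max(1L, round(0.5 * rate))
    v <- c(rep(mean(v[seq_len(min(n_avg, length(v)))]), n_pad), v)
    out <- causal_convolve(v, kernel)[-seq_len(n_pad)]
  } else {
    out <- causal_convolve(v, kernel)
    if (mode == "crop_last5s") {
      n_drop <- round(5 * rate)
      if (n_drop >= length(out)) {
        abort("Trace too short to crop 5 s.", class = "needmot_window_error")
      }
      out <- out[-seq_len(n_drop)]
    }
  }
  out + offset
}

#' Photometry trials
#'
#' A photometry trial couples a (typically z-scored) trace with its sampling
#' rate and event schedule.
#'
#' @param values Numeric signal samples.
#' @param rate Samples per second.
#' @param schedule The trial's [event_schedule()].
#' @param t_align Time of the alignment event (seconds), 0 by convention
#'   after preprocessing.
#' @param zscored Logical flag.
#' @return A tibble of class `"photometry_trial"`.
#' @export
photometry_trial <- function(values, rate, schedule, t_align = 0,
                             zscored = TRUE) {
  if (!all(is.finite(values)) || rate <= 0) {
    abort("Trial values must be finite and rate positive.",
          class = "needmot_input_error")
  }
  w <- schedule_window(schedule)
  out <- tibble(time_s = w[1] + (seq_along(values) - 1) / rate,
                value = as.numeric(values))
  structure(out, rate = rate, schedule = schedule, t_align = t_align,
            zscored = zscored,
            class = c("photometry_trial", class(out)))
}

#' @rdname photometry_trial
#' @param trial A photometry trial.
#' @export
trial_schedule <- function(trial) attr(trial, "schedule")

#' @rdname photometry_trial
#' @export
trial_rate <- function(trial) attr(trial, "rate")

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warn("Zero-variance trace: z-score is degenerate, returning zeros.")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Preprocess raw photometry trials
#'
#' Mirrors the standard photometry pipeline: align each trial so that time 0
#' is the labeled alignment event, z-score over the trial window, up-sample
#' to 100 Hz by linear interpolation, and crop to the window. Raw trials are
#' rows of a long data frame.
#'
#' @param raw A data frame with columns `trial_id`, `time_s`, `value`
#'   (recording clock, any rate).
#' @param events A data frame with columns `trial_id`, `event_label`,
#'   `event_kind`, `time_s` on the same clock.
#' @param align_label Label of the alignment event, present in every trial.
#' @param window Numeric `(start, end)` in seconds relative to the
#'   alignment event.
#' @param rate Output rate, samples per second (default 100).
#' @return A list of [photometry_trial()] objects at `rate`, each with mean
#'   0 and unit variance over the window.
#' @export
preprocess_trials <- function(raw, events, align_label, window, rate = 100) {
  stopifnot(all(c("trial_id", "time_s", "value") %in% names(raw)))
  ids <- unique(raw$trial_id)
  lapply(ids, function(id) {
    d <- raw[raw$trial_id == id, ]
    ev <- events[events$trial_id == id, ]
    t0 <- ev$time_s[ev$event_label == align_label]
    if (length(t0) != 1) {
      abort(sprintf("Trial '%s' is missing alignment event '%s'.",
                    id, align_label),
            class = "needmot_alignment_error")
    }
    t_rel <- d$time_s - t0
    if (window[1] < min(t_rel) - 1e-9 || window[2] > max(t_rel) + 1e-9) {
      abort(sprintf("Window [%g, %g] exceeds trial '%s' recording.",
                    window[1], window[2], id),
            class = "needmot_window_error")
    }
    grid <- sample_grid(window, rate)
    v <- approx(t_rel, d$value, xout = grid, rule = 2)$y
    sched <- event_schedule(
      data.frame(time_s = pmin(pmax(ev$time_s - t0, window[1]), window[2]),
                 label = ev$event_label, kind = ev$event_kind) |>
        (\(x) x[order(x$time_s), ])(),
      window = window)
    photometry_trial(zscore(v), rate = rate, schedule = sched,
                     t_align = 0, zscored = TRUE)
  })
}

#' Average photometry trials
#'
#' Pointwise mean across trials sharing a window and rate (conditional
#' averaging). The averaged trial carries a consensus schedule with the mean
#' event time per event kind/label pair.
#'
#' @param trials List of [photometry_trial()] objects.
#' @return A single [photometry_trial()].
#' @export
average_trials <- function(trials) {
  stopifnot(length(trials) >= 1)
  n <- vapply(trials, nrow, integer(1))
  if (length(unique(n)) != 1) {
    abort("Trials have heterogeneous lengths; align them first.",
          class = "needmot_alignment_error")
  }
  rates <- vapply(trials, trial_rate, numeric(1))
  if (length(unique(rates)) != 1) {
    abort("Trials have heterogeneous rates.",
          class = "needmot_alignment_error")
  }
  vals <- rowMeans(vapply(trials, function(tr) tr$value,
                          numeric(n[1])))
  scheds <- lapply(trials, trial_schedule)
  ev <- do.call(rbind, lapply(scheds, as.data.frame))
  cons <- ev |>
    dplyr::group_by(.data$label, .data$kind) |>
    dplyr::summarise(time_s = mean(.data$time_s), .groups = "drop") |>
    dplyr::arrange(.data$time_s)
  w <- schedule_window(scheds[[1]])
  sched <- event_schedule(as.data.frame(cons[, c("time_s", "label", "kind")]),
                          window = w)
  photometry_trial(vals, rate = rates[1], schedule = sched,
                   t_align = attr(trials[[1]], "t_align"),
                   zscored = all(vapply(trials, function(tr)
                     isTRUE(attr(tr, "zscored")), logical(1))))
}
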