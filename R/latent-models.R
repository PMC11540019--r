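#' Latent traces
#'
#' A latent trace is a uniformly sampled time series of a model latent
#' (need or motivation) over a trial window. Stored as a tibble with columns
#' `time_s` and `value` plus `rate` (samples/s) and `t_start` attributes.
#' Sample `k` sits at `t_start + (k - 1) / rate`; a trace spanning a window
#' of length `L` has `round(L * rate)` samples.
#'
#' @param values Numeric vector of latent values (finite).
#' @param rate Sampling rate in samples per second.
#' @param t_start Time of the first sample, seconds.
#' @return A tibble of class `"latent_trace"`.
#' @export
latent_trace <- function(values, rate = 100, t_start = 0) {
  if (length(values) == 0) {
    abort("A latent trace needs at least one sample.",
          class = "needmot_input_error")
  }
  if (!all(is.finite(values))) {
    abort("Latent trace values must be finite.", class = "needmot_input_error")
  }
  out <- tibble(time_s = t_start + (seq_along(values) - 1) / rate,
                value = as.numeric(values))
  structure(out, rate = rate, t_start = t_start,
            class = c("latent_trace", class(out)))
}

#' @rdname latent_trace
#' @param trace A latent trace.
#' @export
trace_rate <- function(trace) attr(trace, "rate")

#' @rdname latent_trace
#' @export
trace_values <- function(trace) trace$value

#' @rdname latent_trace
#' @export
trace_times <- function(trace) trace$time_s

sample_grid <- function(window, rate) {
  n <- round((window[2] - window[1]) * rate)
  window[1] + (seq_len(n) - 1) / rate
}

#' Build a need trace from an event schedule
#'
#' Need is the predicted deficit: it is piecewise constant, starting at the
#' baseline `n0` and changing by `-R_i` at each predicted-gain or
#' predicted-loss event (`R_i >= 0` for gains, so need steps down; `R_i <= 0`
#' for losses, so need steps up). An abandon event resets need to the
#' pre-trial baseline.
#'
#' @param schedule An [event_schedule()].
#' @param n0 Baseline need at the window start.
#' @param steps Numeric vector of signed step magnitudes `R_i`, one per
#'   gain/loss event of the schedule, in time order.
#' @param rate Samples per second (default 100).
#' @param clip_floor Optional lower bound applied to the trace.
#' @return A [latent_trace()] over the schedule's window.
#' @examples
#' s <- event_schedule(data.frame(time_s = 5, label = "seek", kind = "gain"),
#'                     window = c(0, 10))
#' tr <- build_need_trace(s, n0 = 1, steps = 0.4)
#' range(trace_values(tr)) # 0.6 after the event, 1 before
#' @export
build_need_trace <- function(schedule, n0, steps = numeric(), rate = 100,
                             clip_floor = NULL) {
  sev <- step_events(schedule)
  if (length(steps) != nrow(sev)) {
    abort(sprintf("`steps` has length %d but the schedule has %d step-inducing event(s).",
                  length(steps), nrow(sev)),
          class = "needmot_parameter_error")
  }
  if (any(steps[sev$kind == "gain"] < 0)) {
    abort("Gain events require R >= 0.", class = "needmot_parameter_error")
  }
  if (any(steps[sev$kind == "loss"] > 0)) {
    abort("Loss events require R <= 0.", class = "needmot_parameter_error")
  }
  w <- schedule_window(schedule)
  t <- sample_grid(w, rate)
  v <- rep(n0, length(t))
  step_i <- 0
  for (j in seq_len(nrow(schedule))) {
    kind <- schedule$kind[j]
    tau <- schedule$time_s[j]
    if (kind %in% c("gain", "loss")) {
      step_i <- step_i + 1
      v[t >= tau] <- v[t >= tau] - steps[step_i]
    } else if (kind == "abandon") {
      v[t >= tau] <- n0
    }
  }
  if (!is.null(clip_floor)) v <- pmax(v, clip_floor)
  latent_trace(v, rate = rate, t_start = w[1])
}

# Piecewise-constant view of need over the window: breakpoints at t0, event
# times and the window end; segment values read from the sampled trace just
# after each breakpoint. Exact provided consecutive events are more than one
# sample apart.
need_segments <- function(schedule, need, t0, t_end = NULL) {
  w <- schedule_window(schedule)
  t_end <- t_end %||% w[2]
  rate <- trace_rate(need)
  brk <- sort(unique(c(t0, schedule$time_s[schedule$time_s > t0 &
                                             schedule$time_s < t_end], t_end)))
  v <- trace_values(need)
  t <- trace_times(need)
  seg_val <- vapply(brk[-length(brk)], function(b) {
    i <- which(t >= b - 1e-9)[1]
    if (is.na(i)) v[length(v)] else v[i]
  }, numeric(1))
  list(breaks = brk, values = seg_val)
}

#' Build a motivation trace as the leaky accumulation of need
#'
#' Motivation is `M(t) = m0` before `t0` (the accessibility moment) and
#' `M(t) = m0 + integral_{t0}^{t} [a * N(s) - leak] ds` afterwards. Because
#' need is piecewise constant, the integral is evaluated in closed form as a
#' continuous piecewise-linear function whose slope on each interval is
#' `a * N - leak`. An abandon event resets motivation to the pre-trial
#' baseline (or to zero, see `abandon_reset`) and stops further accumulation.
#' Accumulation also stops at `accumulate_until` (e.g. the consumption-end
#' moment), after which only the leak term continues.
#'
#' @param schedule An [event_schedule()].
#' @param need A [latent_trace()] of need over the same window and rate.
#' @param m0 Baseline motivation.
#' @param a Accumulation gain (>= 0).
#' @param leak Constant decay rate (>= 0).
#' @param t0 Accumulation onset in seconds; `NULL` uses the schedule's
#'   accessibility event, and if there is none the trace is flat at `m0`.
#' @param accumulate_until End of the accumulation window; `NULL` uses the
#'   schedule's consumption-end event if present, else the window end.
#' @param abandon_reset `"baseline"` (reset to `m0`, default) or `"zero"`.
#' @param rate Samples per second; must match `need`.
#' @return A [latent_trace()].
#' @export
build_motivation_trace <- function(schedule, need, m0 = 0, a = 1, leak = 0,
                                   t0 = NULL, accumulate_until = NULL,
                                   abandon_reset = c("baseline", "zero"),
                                   rate = trace_rate(need)) {
  abandon_reset <- match.arg(abandon_reset)
  if (!isTRUE(all.equal(rate, trace_rate(need)))) {
    abort("`need` and the requested output rate differ.",
          class = "needmot_alignment_error")
  }
  if (a < 0 || leak < 0 || !is.finite(a) || !is.finite(leak)) {
    abort("`a` and `leak` must be finite and non-negative.",
          class = "needmot_parameter_error")
  }
  w <- schedule_window(schedule)
  t <- sample_grid(w, rate)
  if (length(t) != nrow(need)) {
    abort("`need` does not span the schedule window at this rate.",
          class = "needmot_alignment_error")
  }
  if (is.null(t0)) {
    acc <- schedule$time_s[schedule$kind == "accessibility"]
    if (length(acc) == 0) {
      return(latent_trace(rep(m0, length(t)), rate = rate, t_start = w[1]))
    }
    t0 <- acc[1]
  }
  if (t0 < w[1]) {
    abort("`t0` must lie within the trial window.",
          class = "needmot_parameter_error")
  }
  if (is.null(accumulate_until)) {
    ce <- schedule$time_s[schedule$kind == "consumption_end"]
    accumulate_until <- if (length(ce) > 0) ce[1] else w[2]
  }
  abn <- schedule$time_s[schedule$kind == "abandon"]
  t_abandon <- if (length(abn) > 0) abn[1] else Inf

  v <- rep(m0, length(t))
  seg <- need_segments(schedule, need, t0)
  m_at <- m0
  for (j in seq_along(seg$values)) {
    b0 <- seg$breaks[j]
    b1 <- seg$breaks[j + 1]
    if (b0 >= t_abandon) break
    b1 <- min(b1, t_abandon)
    # accumulation term active only inside [t0, accumulate_until]
    slope_full <- a * seg$values[j] - leak
    idx <- t >= b0 & t < b1 + 1e-12
    if (b1 <= accumulate_until) {
      v[idx] <- m_at + slope_full * (t[idx] - b0)
      m_at <- m_at + slope_full * (b1 - b0)
    } else if (b0 >= accumulate_until) {
      v[idx] <- m_at - leak * (t[idx] - b0)
      m_at <- m_at - leak * (b1 - b0)
    } else {
      split_t <- accumulate_until
      m_split <- m_at + slope_full * (split_t - b0)
      pre <- idx & t < split_t
      post <- idx & t >= split_t
      v[pre] <- m_at + slope_full * (t[pre] - b0)
      v[post] <- m_split - leak * (t[post] - split_t)
      m_at <- m_split - leak * (b1 - split_t)
    }
  }
  if (is.finite(t_abandon)) {
    v[t >= t_abandon] <- if (abandon_reset == "baseline") m0 else 0
  }
  latent_trace(v, rate = rate, t_start = w[1])
}

#' Invert a latent trace about its initial value
#'
#' The inverted-sign control reflects excursions about the trace's first
#' sample: `v -> 2 * v[1] - v`. The initial value is preserved and the
#' operation is an involution. Used to build the "inverted need" and
#' "inverted motivation" candidate latents that test whether one neural
#' population merely mirrors the other.
#'
#' @param trace A [latent_trace()].
#' @return A [latent_trace()] with flipped excursions.
#' @export
build_inverted_trace <- function(trace) {
  v <- trace_values(trace)
  if (length(v) == 0) {
    abort("Cannot invert an empty trace.", class = "needmot_input_error")
  }
  latent_trace(2 * v[1] - v, rate = trace_rate(trace),
               t_start = attr(trace, "t_start"))
}

#' Test identifiers
#' @format NULL
#' @export
TEST_IDS <- c("gain1", "gain2", "loss1", "loss2", "loss3",
              "multi_gain", "multi_gain_loss")

#' Latent model names
#' @format NULL
#' @export
MODEL_NAMES <- c("need", "motivation", "inverted_need", "inverted_motivation")

check_test_vocabulary <- function(test_id, schedule) {
  kinds <- schedule$kind
  req <- switch(test_id,
    gain1 = ,
    gain2 = "gain",
    loss1 = "loss",
    loss2 = ,
    loss3 = c("gain", "abandon"),
    multi_gain = "gain",
    multi_gain_loss = c("gain", "consumption_end", "loss"))
  missing <- setdiff(req, kinds)
  if (length(missing) > 0) {
    abort(sprintf("Test '%s' requires event kind(s): %s.",
                  test_id, paste(missing, collapse = ", ")),
          class = "needmot_schedule_error")
  }
  if (test_id == "loss1" && any(kinds == "gain")) {
    abort("Test 'loss1' has only a loss event.",
          class = "needmot_schedule_error")
  }
  invisible(TRUE)
}

#' Shift the consumption-end event of a schedule
#'
#' Accounts for residual food in the mouth: the observed consumption-end
#' label can lag the true end of consummatory behavior, so model fits probe
#' delays of 0-8 s.
#'
#' @param schedule An [event_schedule()].
#' @param delay_s Non-negative shift in seconds.
#' @return A new [event_schedule()] with the consumption-end time shifted.
#' @export
shift_consumption_end <- function(schedule, delay_s) {
  if (delay_s == 0) return(schedule)
  i <- which(schedule$kind == "consumption_end")
  if (length(i) == 0) {
    abort("Schedule has no consumption_end event to shift.",
          class = "needmot_schedule_error")
  }
  ev <- as.data.frame(schedule)
  ev$time_s[i] <- ev$time_s[i] + delay_s
  ev <- ev[order(ev$time_s), ]
  event_schedule(ev, schedule_window(schedule))
}

#' Build a per-test candidate latent
#'
#' Dispatches to the need/motivation builders with the per-test constraints:
#' `loss1` carries a single loss event (need steps up, motivation stays flat
#' because inaccessibility blocks access to the goal); `loss2`/`loss3` apply
#' the return-to-baseline abandon rule; `multi_gain_loss` optionally shifts
#' the consumption-end event by `delay_s` before latent construction.
#' Inverted variants reflect the corresponding latent about its initial
#' value.
#'
#' @param test_id One of `r paste0('"', TEST_IDS, '"', collapse = ", ")`.
#' @param schedule An [event_schedule()] matching the test's vocabulary.
#' @param model One of `r paste0('"', MODEL_NAMES, '"', collapse = ", ")`.
#' @param params Named list. For need-family models: `n0`, `steps`,
#'   optionally `clip_floor`. For motivation-family models: `m0`, `a`,
#'   `leak`, plus `n0`/`steps` for the underlying need (loss steps are
#'   dropped for motivation: predicted loss does not feed accumulation).
#' @param rate Samples per second.
#' @param delay_s Consumption-end delay in `[0, 8]` seconds
#'   (multi_gain_loss only).
#' @return A [latent_trace()].
#' @export
build_test_model <- function(test_id, schedule, model, params, rate = 100,
                             delay_s = 0) {
  test_id <- match.arg(test_id, TEST_IDS)
  model <- match.arg(model, MODEL_NAMES)
  check_test_vocabulary(test_id, schedule)
  if (delay_s != 0) {
    if (test_id != "multi_gain_loss") {
      abort("A consumption-end delay applies only to 'multi_gain_loss'.",
            class = "needmot_parameter_error")
    }
    if (delay_s < 0 || delay_s > 8) {
      abort("`delay_s` must lie in [0, 8] seconds.",
            class = "needmot_parameter_error")
    }
    schedule <- shift_consumption_end(schedule, delay_s)
  }
  base <- if (model %in% c("need", "inverted_need")) {
    build_need_trace(schedule, n0 = params$n0,
                     steps = params$steps %||% numeric(),
                     rate = rate, clip_floor = params$clip_floor)
  } else {
    sev <- step_events(schedule)
    steps <- params$steps %||% numeric()
    # predicted loss does not feed accumulation: the blocked goal leaves
    # motivation unchanged, so loss steps are zeroed in the driving need
    steps[sev$kind == "loss"] <- 0
    need <- build_need_trace(schedule, n0 = params$n0 %||% 1,
                             steps = steps, rate = rate)
    build_motivation_trace(schedule, need,
                           m0 = params$m0 %||% 0,
                           a = params$a %||% 1,
                           leak = params$leak %||% 0,
                           abandon_reset = params$abandon_reset %||% "baseline",
                           rate = rate)
  }
  if (model %in% c("inverted_need", "inverted_motivation")) {
    base <- build_inverted_trace(base)
  }
  base
}
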