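#' Event schedules
#'
#' An event schedule is the backbone of every trial: an ordered set of
#' labeled, timestamped events (accessibility, predicted-gain events such as
#' seeking initiation or food contact, predicted-loss events such as
#' inaccessibility, eating abandon, consumption end) inside a trial window.
#' Latent need/motivation time courses are constructed from it.
#'
#' @param events A data frame with columns `time_s` (seconds, strictly
#'   increasing), `label` (free text) and `kind` (one of
#'   `r paste0('"', EVENT_KINDS, '"', collapse = ", ")`).
#' @param window Numeric length-2, trial window `(start, end)` in seconds.
#' @return A tibble of class `"event_schedule"` with a `window` attribute.
#' @examples
#' sched <- event_schedule(
#'   data.frame(time_s = c(10, 13), label = c("door", "seek"),
#'              kind = c("accessibility", "gain")),
#'   window = c(0, 30))
#' @export
event_schedule <- function(events, window) {
  stopifnot(is.data.frame(events))
  need_cols <- c("time_s", "label", "kind")
  if (!all(need_cols %in% names(events))) {
    abort(paste("`events` must have columns:", paste(need_cols, collapse = ", ")),
          class = "needmot_schedule_error")
  }
  if (!is.numeric(window) || length(window) != 2 || !(window[1] < window[2])) {
    abort("`window` must be numeric (start, end) with start < end.",
          class = "needmot_schedule_error")
  }
  ev <- tibble::as_tibble(events[, need_cols])
  ev$kind <- as.character(ev$kind)
  ev$label <- as.character(ev$label)
  bad_kind <- setdiff(ev$kind, EVENT_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown event kind(s): ", paste(bad_kind, collapse = ", ")),
          class = "needmot_schedule_error")
  }
  if (nrow(ev) > 1 && any(diff(ev$time_s) <= 0)) {
    abort("Event times must be strictly increasing.",
          class = "needmot_schedule_error")
  }
  if (any(ev$time_s < window[1] | ev$time_s > window[2])) {
    abort("All event times must lie within the trial window.",
          class = "needmot_schedule_error")
  }
  acc <- which(ev$kind == "accessibility")
  if (length(acc) > 1) {
    abort("At most one accessibility event is allowed.",
          class = "needmot_schedule_error")
  }
  if (length(acc) == 1 && any(ev$kind == "gain") &&
      ev$time_s[acc] > min(ev$time_s[ev$kind == "gain"])) {
    abort("The accessibility event must precede all gain events.",
          class = "needmot_schedule_error")
  }
  structure(ev, window = as.numeric(window),
            class = c("event_schedule", class(ev)))
}

#' @rdname event_schedule
#' @format NULL
#' @export
EVENT_KINDS <- c("accessibility", "gain", "loss", "abandon",
                 "consumption_end", "trial_start", "trial_end")

#' @export
print.event_schedule <- function(x, ...) {
  w <- schedule_window(x)
  cat(sprintf("<event_schedule> window [%g, %g] s, %d event(s)\n",
              w[1], w[2], nrow(x)))
  NextMethod()
}

#' Trial window of a schedule
#' @param schedule An [event_schedule()].
#' @return Numeric length-2 `(start, end)` in seconds.
#' @export
schedule_window <- function(schedule) attr(schedule, "window")

#' Events of a schedule that induce a step in need
#'
#' Gain and loss events carry a free step magnitude; abandon events reset the
#' latent to its pre-trial baseline and carry none.
#' @inheritParams schedule_window
#' @return The schedule rows with `kind` in `gain`/`loss`, in time order.
#' @export
step_events <- function(schedule) {
  schedule[schedule$kind %in% c("gain", "loss"), , drop = FALSE]
}

#' Read / write event tables
#'
#' Plain-text event tables use columns `trial_id`, `event_label`,
#' `event_kind`, `time_s` (seconds, 0 = trial-window start).
#'
#' @param path File path (CSV; use `sep = "\t"` for TSV).
#' @param window Trial window applied to every trial.
#' @param sep Field separator.
#' @return `read_event_table()`: a named list of [event_schedule()] objects,
#'   one per `trial_id`.
#' @export
read_event_table <- function(path, window, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need_cols <- c("trial_id", "event_label", "event_kind", "time_s")
  if (!all(need_cols %in% names(df))) {
    abort(paste("Event table must have columns:",
                paste(need_cols, collapse = ", ")),
          class = "needmot_io_error")
  }
  split(df, df$trial_id) |>
    lapply(function(d) {
      d <- d[order(d$time_s), ]
      event_schedule(
        data.frame(time_s = d$time_s, label = d$event_label,
                   kind = d$event_kind),
        window = window)
    })
}

#' @rdname read_event_table
#' @param schedules Named list of [event_schedule()] objects.
#' @export
write_event_table <- function(schedules, path, sep = ",") {
  rows <- imap(schedules, function(s, id) {
    data.frame(trial_id = id, event_label = s$label,
               event_kind = s$kind, time_s = s$time_s)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
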