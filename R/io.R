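#' Load and validate a run configuration
#'
#' Configurations are YAML or JSON with a strict schema: top-level keys
#' `command` (one of `generate`, `fit`, `behavior-fit`, `simulate`,
#' `compare`, `sweep`), `paths` (named file locations), `parameters`
#' (nested named values), `seed` (integer; required for every stochastic
#' command) and `log_level`. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `"run_config"` with defaults applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' not found.", path),
          class = "needmot_config_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  allowed <- c("command", "paths", "parameters", "seed", "log_level")
  commands <- c("generate", "fit", "behavior-fit", "simulate", "compare",
                "sweep")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "needmot_config_error")
  }
  if (is.null(cfg$command) || !cfg$command %in% commands) {
    abort(sprintf("`command` must be one of: %s.",
                  paste(commands, collapse = ", ")),
          class = "needmot_config_error")
  }
  stochastic <- c("generate", "fit", "behavior-fit", "simulate", "sweep",
                  "compare")
  if (cfg$command %in% stochastic && is.null(cfg$seed)) {
    abort(sprintf("Field `seed` is required for command '%s'.",
                  cfg$command),
          class = "needmot_config_error")
  }
  cfg$paths <- cfg$paths %||% list()
  cfg$parameters <- cfg$parameters %||% list()
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

#' Read / write latent or photometry traces as columnar text
#'
#' @param trace A [latent_trace()] or [photometry_trial()].
#' @param path CSV file path.
#' @return `read_trace_csv()`: a tibble with columns `time_s`, `value` and
#'   a `rate` attribute.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, value = trace$value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g", attr(trace, "rate")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1)
  rate <- if (grepl("^# rate_hz=", first)) {
    as.numeric(sub("^# rate_hz=", "", first))
  } else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  structure(tibble::as_tibble(df), rate = rate)
}

#' Fit and compare candidate latent models across trials
#'
#' Fits every requested candidate model to each trial (or to the trial
#' average), assembles the trials-by-models AIC matrix, and runs the
#' Friedman rank test across trials when there are enough of them. The
#' model with the lowest (mean) AIC wins. Optionally writes a JSON report
#' and a CSV AIC table.
#'
#' @param trials List of [photometry_trial()] objects from one session.
#' @param models Character vector (>= 2) of candidate models, a subset of
#'   `r paste0('"', MODEL_NAMES, '"', collapse = ", ")`.
#' @param test_id The behavioral test the trials come from.
#' @param kernel Calcium kernel at the trials' rate.
#' @param mode Boundary handling for the fits.
#' @param per_trial Fit each trial (`TRUE`) or the average (`FALSE`)?
#' @param n_starts,seed,maxit Optimizer settings.
#' @param out_dir Optional directory for `report.json` / `aic.csv`.
#' @return A list of class `"needmot_session_comparison"`: `aic_matrix`,
#'   `winner`, `mean_aic`, `friedman`, `fits`.
#' @export
run_compare <- function(trials, models = c("need", "motivation"),
                        test_id, kernel = NULL,
                        mode = c("pad_mean", "crop_last5s", "none"),
                        per_trial = TRUE, n_starts = 10, seed = 1,
                        maxit = 200, out_dir = NULL) {
  mode <- match.arg(mode)
  if (length(models) < 2) {
    abort("Need at least two candidate models.",
          class = "needmot_config_error")
  }
  models <- vapply(models, function(m) match.arg(m, MODEL_NAMES),
                   character(1))
  rate <- trial_rate(trials[[1]])
  kernel <- kernel %||% gcamp_kernel(rate = rate)
  units <- if (per_trial) trials else list(average_trials(trials))
  fits <- lapply(units, function(tr) {
    lapply(setNames(models, models), function(m) {
      spec <- latent_model_spec(test_id, m, trial_schedule(tr), kernel,
                                rate = rate, mode = mode)
      fit_model(tr, spec, n_starts = n_starts, seed = seed, maxit = maxit)
    })
  })
  aic_matrix <- do.call(rbind, lapply(fits, function(fs) {
    vapply(fs, function(f) f$aic, numeric(1))
  }))
  rownames(aic_matrix) <- paste0("unit", seq_len(nrow(aic_matrix)))
  mean_aic <- colMeans(aic_matrix)
  friedman <- if (nrow(aic_matrix) >= 2) friedman_on_aic(aic_matrix)
    else NULL
  out <- structure(
    list(aic_matrix = aic_matrix, mean_aic = mean_aic,
         winner = names(which.min(mean_aic)), friedman = friedman,
         fits = fits, seed = seed, models = models),
    class = "needmot_session_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(winner = out$winner,
                   mean_aic = as.list(mean_aic),
                   friedman_statistic = friedman$statistic %||% NA,
                   friedman_p = friedman$p %||% NA,
                   seed = seed, models = as.list(unname(models)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.csv(as.data.frame(aic_matrix),
                     file.path(out_dir, "aic.csv"))
  }
  out
}

#' @export
print.needmot_session_comparison <- function(x, ...) {
  cat(sprintf("<needmot_session_comparison> winner '%s' over %d unit(s)\n",
              x$winner, nrow(x$aic_matrix)))
  print(round(x$mean_aic, 3))
  if (!is.null(x$friedman)) {
    cat(sprintf("Friedman chi^2 = %.3g, p = %.3g (%s)\n",
                x$friedman$statistic, x$friedman$p, x$friedman$method))
  }
  invisible(x)
}
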