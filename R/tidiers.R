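#' Tidy a model fit
#'
#' @param x A `"needmot_fit"` from [fit_model()] or [fit_behavior()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.needmot_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.needmot_fit
#' @return `glance()`: a one-row tibble of fit summaries.
#' @export
glance.needmot_fit <- function(x, ...) {
  tibble(model = x$model_name, rmse = x$rmse, rss = x$rss, n = x$n,
         k = x$k, aic = x$aic, n_starts = x$n_starts, seed = x$seed,
         converged = x$converged)
}

#' Tidy a model comparison
#'
#' @param x A `"needmot_comparison"` from [compare_fits()].
#' @param ... Unused.
#' @return A tibble with one row per candidate model.
#' @export
tidy.needmot_comparison <- function(x, ...) {
  tibble(model = names(x$aic), aic = unname(x$aic),
         winner = names(x$aic) == x$winner) |>
    dplyr::arrange(.data$aic)
}

#' @rdname tidy.needmot_comparison
#' @export
glance.needmot_comparison <- function(x, ...) {
  tibble(winner = x$winner, delta_aic = x$delta_aic,
         n_models = length(x$aic))
}

#' Tidy a session comparison
#'
#' @param x A `"needmot_session_comparison"` from [run_compare()].
#' @param ... Unused.
#' @return A tibble in long format: one row per (unit, model) AIC.
#' @export
tidy.needmot_session_comparison <- function(x, ...) {
  m <- x$aic_matrix
  tibble(unit = rep(rownames(m), times = ncol(m)),
         model = rep(colnames(m), each = nrow(m)),
         aic = as.vector(m))
}

#' @rdname tidy.needmot_session_comparison
#' @export
glance.needmot_session_comparison <- function(x, ...) {
  tibble(winner = x$winner, n_units = nrow(x$aic_matrix),
         friedman_statistic = x$friedman$statistic %||% NA_real_,
         friedman_p = x$friedman$p %||% NA_real_)
}
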