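#' Plot a latent trace
#'
#' @param object A [latent_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.latent_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Latent value") +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted series of a model fit
#'
#' @param object A `"needmot_fit"`.
#' @param ... Unused.
#' @return A ggplot overlaying the observed series (grey) and the model
#'   prediction (colored by model name).
#' @export
autoplot.needmot_fit <- function(object, ...) {
  df <- tibble(index = seq_along(object$observed),
               observed = object$observed, fitted = object$fitted) |>
    tidyr::pivot_longer(c("observed", "fitted"), names_to = "series",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(observed = "grey50",
                                           fitted = "#d26a8a")) +
    ggplot2::labs(x = "Sample", y = "Signal (z)",
                  title = sprintf("%s model fit (RMSE %.3g, AIC %.3g)",
                                  object$model_name, object$rmse,
                                  object$aic)) +
    ggplot2::theme_minimal()
}

#' Plot an agent trajectory
#'
#' Shows deficit, need and motivation over time with go bouts shaded.
#'
#' @param object An `"agent_trajectory"` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agent_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("t", "deficit", "need", "motivation")],
    c("deficit", "need", "motivation"),
    names_to = "variable", values_to = "value")
  go <- object[object$action == "go", ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                        color = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time step", y = "Value",
                  title = sprintf("%s / %s (acquisition at %s)",
                                  attr(object, "policy"),
                                  attr(object, "condition"),
                                  attr(object, "acquisition_time"))) +
    ggplot2::theme_minimal()
  if (nrow(go) > 0) {
    p <- p + ggplot2::geom_rug(data = go, ggplot2::aes(x = .data$t),
                               inherit.aes = FALSE, sides = "b",
                               alpha = 0.2)
  }
  p
}
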