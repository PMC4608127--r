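#' Plot a fitted neighbor-weight profile
#'
#' Coefficient against window offset; a fitted profile typically
#' decreases roughly linearly and symmetrically away from the center.
#'
#' @param weights a [window_weights] object.
#' @return A ggplot object.
#' @export
plot_weight_profile <- function(weights) {
  d <- tidy(weights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "window offset", y = "coefficient",
                  title = sprintf("neighbor influence, N = %d", weights$window)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.window_weights <- function(object, ...) {
  plot_weight_profile(object)
}

#' Diagnostic plots of an evaluation report
#'
#' `plot_error_bands()` shows the share of residues per absolute-error
#' band; `plot_per_type()` compares true and predicted mean RSA per
#' residue type with the per-type error; `plot_two_state()` draws
#' two-state accuracy against the exposure threshold.
#' `autoplot()` dispatches on `which`.
#'
#' @param x an `rsa_eval` object (see [evaluate_predictions()]).
#' @return A ggplot object.
#' @export
plot_error_bands <- function(x) {
  d <- x$error_bands
  d$share <- 100 * d$count / sum(d$count)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$band, levels = .data$band),
                                  y = .data$share)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "absolute error band (%)", y = "residues (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_error_bands
#' @export
plot_per_type <- function(x) {
  d <- tidyr::pivot_longer(x$per_type, c("mean_true", "mean_pred"),
                           names_to = "track", values_to = "rsa")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$rsa,
                                  fill = .data$track)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue type", y = "mean RSA (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_error_bands
#' @export
plot_two_state <- function(x) {
  ggplot2::ggplot(x$two_state, ggplot2::aes(x = .data$threshold,
                                            y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "exposure threshold (%)", y = "two-state accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @param object an `rsa_eval` object.
#' @param which one of `"error_bands"`, `"per_type"`, `"two_state"`.
#' @param ... unused.
#' @rdname plot_error_bands
#' @export
autoplot.rsa_eval <- function(object, which = c("error_bands", "per_type",
                                                "two_state"), ...) {
  which <- match.arg(which)
  switch(which,
         error_bands = plot_error_bands(object),
         per_type = plot_per_type(object),
         two_state = plot_two_state(object))
}
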