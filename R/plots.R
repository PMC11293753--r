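# ggplot2 presentation layer.

#' Plot an observation run
#'
#' Citizen counts over time with the legitimacy and propaganda forcing in a
#' lower panel.
#'
#' @param table Observation tibble.
#' @return A ggplot object.
#' @export
plot_run <- function(table) {
  long <- tidyr::pivot_longer(
    table, dplyr::all_of(c("Quiet", "Active", "Jailed", "Legitimacy", "Propaganda")),
    names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series %in% c("Legitimacy", "Propaganda"),
                       "forcing", "counts")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname edm_predict
#' @param object An `edm_forecast`.
#' @export
autoplot.edm_forecast <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs, c("observed", "predicted"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time step", y = object$spec$target,
                  title = sprintf("%s forecast, Tp = %d, rho = %.3f",
                                  object$method, object$Tp, object$skill)) +
    ggplot2::theme_minimal()
}

#' @rdname scan_embedding_dimension
#' @param object An `edm_scan`.
#' @export
autoplot.edm_scan <- function(object, ...) {
  grid <- tibble::as_tibble(unclass(object))
  along <- attr(object, "along") %||% "E"
  other <- if (along == "E") "Tp" else "E"
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[along]], y = .data$skill,
                                     colour = factor(.data[[other]]))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(colour = other, y = "prediction skill (Pearson rho)") +
    ggplot2::theme_minimal()
}

#' @rdname coefficient_series
#' @param object A `coefficient_series`.
#' @export
autoplot.coefficient_series <- function(object, ...) {
  long <- tidy.coefficient_series(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "time step", y = "s-map coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname jacobian_variance_by_regime
#' @param object A `regime_variance`.
#' @export
autoplot.regime_variance <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variance, fill = .data$regime)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "windowed variance of dActive/dPropaganda",
                  y = "density", fill = "legitimacy regime") +
    ggplot2::theme_minimal()
}

#' @rdname propaganda_response
#' @param params Parameters from [controller_params()].
#' @param from,to Range of predicted Active counts to display.
#' @export
plot_controller <- function(params = controller_params(), from = -50, to = 200) {
  A <- seq(from, to, length.out = 400)
  df <- tibble::tibble(A_pred = A, P = propaganda_response(A, params))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$A_pred, y = .data$P)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(params$P_min, params$P_max),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "predicted Active citizens", y = "propaganda level") +
    ggplot2::theme_minimal()
}
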