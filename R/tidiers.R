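# broom-style tidiers for the package's result objects.

#' @rdname edm_predict
#' @param x An `edm_forecast`.
#' @param ... Unused.
#' @export
tidy.edm_forecast <- function(x, ...) x$pairs

#' @rdname edm_predict
#' @export
glance.edm_forecast <- function(x, ...) {
  tibble::tibble(
    skill = x$skill,
    n_pairs = sum(is.finite(x$pairs$observed) & is.finite(x$pairs$predicted)),
    Tp = x$Tp, method = x$method, theta = x$theta, k = x$k)
}

#' @rdname scan_embedding_dimension
#' @param x An `edm_scan`.
#' @param ... Unused.
#' @export
tidy.edm_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname scan_embedding_dimension
#' @export
glance.edm_scan <- function(x, ...) skill_saturation(x)

#' @rdname select_theta
#' @param x A `theta_selection`.
#' @param ... Unused.
#' @export
tidy.theta_selection <- function(x, ...) x$grid

#' @rdname select_theta
#' @export
glance.theta_selection <- function(x, ...) {
  tibble::tibble(theta = x$theta,
                 skill = x$grid$skill[match(x$theta, x$grid$theta)])
}

#' @rdname smap_predict
#' @param x An `smap_solution`.
#' @param ... Unused.
#' @export
tidy.smap_solution <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname coefficient_series
#' @param x A `coefficient_series`.
#' @param ... Unused.
#' @export
tidy.coefficient_series <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"time",
                      names_to = "term", values_to = "estimate")
}

#' @rdname coefficient_series
#' @export
glance.coefficient_series <- function(x, ...) {
  long <- tidy.coefficient_series(x)
  dplyr::summarise(dplyr::group_by(long, .data$term),
                   mean = mean(.data$estimate, na.rm = TRUE),
                   sd = stats::sd(.data$estimate, na.rm = TRUE),
                   .groups = "drop")
}

#' @rdname detect_episodes
#' @param x An `episode_table`.
#' @param ... Unused.
#' @export
tidy.episode_table <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname detect_episodes
#' @export
glance.episode_table <- function(x, ...) {
  ks <- episode_waiting_ks(x)
  tibble::tibble(n_episodes = nrow(x), mean_peak = mean(x$peak),
                 mean_wait = ks$mean_wait, ks_statistic = ks$ks_statistic,
                 ks_p_value = ks$p_value)
}

#' @rdname jacobian_variance_by_regime
#' @param x A `regime_variance`.
#' @param ... Unused.
#' @export
tidy.regime_variance <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname jacobian_variance_by_regime
#' @export
glance.regime_variance <- function(x, ...) {
  lowv <- x$variance[x$regime == "low"]
  highv <- x$variance[x$regime == "high"]
  test <- if (length(lowv) >= 1 && length(highv) >= 1) {
    suppressWarnings(stats::wilcox.test(lowv, highv, alternative = "greater"))
  } else NULL
  tibble::tibble(
    n_low = length(lowv), n_high = length(highv),
    median_low = stats::median(lowv), median_high = stats::median(highv),
    rank_p_value = if (is.null(test)) NA_real_ else test$p.value)
}
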