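# Post-hoc analyses: rebellion-episode statistics, trapped-state detection,
# the train/test forecast-skill protocol, and the variance of the
# propaganda Jacobian partitioned by legitimacy regime.

#' Detect rebellion episodes
#'
#' An episode is a maximal run of steps with `Active > active_threshold`;
#' episodes separated by fewer than `min_gap` sub-threshold steps are merged.
#' Waiting times are the gaps between consecutive episode starts.
#'
#' @param table Observation tibble.
#' @param active_threshold Active-count threshold defining an episode
#'   (default 50, the controller midpoint).
#' @param min_gap Merge episodes closer than this many steps.
#' @return An `episode_table`: tibble with `start`, `end`, `duration`,
#'   `peak`; inter-episode waiting times in the `waiting_times` attribute.
#' @export
detect_episodes <- function(table, active_threshold = 50, min_gap = 20) {
  stopifnot("Active" %in% names(table), "time" %in% names(table))
  above <- table$Active > active_threshold
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(ep) > 1) {
    merged <- ep[1, ]
    for (i in 2:nrow(ep)) {
      if (ep$start[i] - merged$end[nrow(merged)] - 1L < min_gap) {
        merged$end[nrow(merged)] <- ep$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, ep[i, ])
      }
    }
    ep <- merged
  }
  if (nrow(ep) > 0) {
    ep$start <- table$time[ep$start]
    ep$end <- table$time[ep$end]
    ep$duration <- ep$end - ep$start + 1L
    ep$peak <- purrr::map2_dbl(ep$start, ep$end, function(s, e)
      max(table$Active[table$time >= s & table$time <= e]))
  } else {
    ep <- tibble::tibble(start = integer(), end = integer(),
                         duration = integer(), peak = numeric())
  }
  class(ep) <- c("episode_table", class(ep))
  attr(ep, "waiting_times") <- if (nrow(ep) > 1) diff(ep$start) else numeric(0)
  attr(ep, "active_threshold") <- active_threshold
  attr(ep, "min_gap") <- min_gap
  ep
}

#' Kolmogorov-Smirnov check of exponential waiting times
#'
#' Punctuated equilibrium implies approximately exponential inter-episode
#' waiting times; this fits an exponential by the sample mean and runs a KS
#' test against it.
#'
#' @param episodes An `episode_table` from [detect_episodes()].
#' @return Tibble with `n_waits`, `mean_wait`, `ks_statistic`, `p_value`.
#' @export
episode_waiting_ks <- function(episodes) {
  w <- attr(episodes, "waiting_times")
  if (length(w) < 3) {
    return(tibble::tibble(n_waits = length(w), mean_wait = NA_real_,
                          ks_statistic = NA_real_, p_value = NA_real_))
  }
  ks <- suppressWarnings(stats::ks.test(w, "pexp", rate = 1 / mean(w)))
  tibble::tibble(n_waits = length(w), mean_wait = mean(w),
                 ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Detect a trapped state of sustained rebellion
#'
#' A run is trapped when the Active fraction exceeds `frac_threshold` for at
#' least `duration` consecutive steps.
#'
#' @param table Observation tibble.
#' @param frac_threshold Active fraction of the citizen population (default
#'   0.25).
#' @param duration Minimum consecutive steps above the threshold (default
#'   200).
#' @param n_citizens Citizen population; taken from the table's
#'   `n_citizens` attribute when present, else 1200.
#' @return Tibble with `trapped` (logical) and `onset` (first step of the
#'   qualifying stretch, `NA` when not trapped).
#' @export
detect_trapped_state <- function(table, frac_threshold = 0.25, duration = 200,
                                 n_citizens = NULL) {
  n_citizens <- n_citizens %||% attr(table, "n_citizens") %||% 1200L
  above <- table$Active / n_citizens > frac_threshold
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= duration)
  tibble::tibble(
    trapped = length(hit) > 0,
    onset = if (length(hit) > 0) table$time[starts[hit[1]]] else NA_integer_)
}

#' Train/test forecast-skill protocol
#'
#' Builds the state-space library from the training rows only, selects the
#' s-map localization on an internal split of the training rows, predicts the
#' target over the test rows at the spec's horizon, and returns the forecast
#' (its Pearson skill via [glance()]). Test rows are never read during
#' library construction or localization selection.
#'
#' @param table Observation tibble (3100 rows for the canonical protocol).
#' @param spec Embedding; default the 6-dimensional Quiet/Jailed embedding at
#'   `Tp = 5`.
#' @param train,test Inclusive 1-based row ranges; defaults `(1, 1500)` and
#'   `(1601, 3100)`.
#' @param theta_grid Candidate localization grid.
#' @param select_frac Fraction of the training rows used as library during
#'   localization selection.
#' @return An `edm_forecast` with the selected `theta` attached.
#' @export
skill_protocol <- function(table, spec = generalized_embedding(Tp = 5L),
                           train = c(1, 1500), test = c(1601, 3100),
                           theta_grid = default_theta_grid(),
                           select_frac = 0.7) {
  train <- check_range(train, nrow(table), "train")
  test <- check_range(test, nrow(table), "test")
  if (train[2] >= test[1] && test[2] >= train[1]) {
    abort_config("train and test row ranges must not overlap")
  }
  split_at <- train[1] - 1L + floor(select_frac * (train[2] - train[1] + 1L))
  sel <- select_theta(table, spec, theta_grid,
                      lib = c(train[1], split_at),
                      pred = c(split_at + 1L, train[2]))
  fc <- edm_predict(table, spec, lib = train, pred = test, method = "smap",
                    theta = sel$theta)
  attr(fc, "theta_selection") <- sel
  fc
}

#' Variance of the propaganda Jacobian by legitimacy regime
#'
#' Slides a window along the propaganda-coefficient series, computes the
#' within-window variance of the coefficient, labels each window low or high
#' legitimacy by its mean legitimacy against `threshold` (windows exactly at
#' the threshold count as high), and compares the two variance populations.
#'
#' @param coeffs A `coefficient_series` including a Propaganda coordinate.
#' @param table The observation tibble the coefficients came from (supplies
#'   per-step legitimacy, joined by time).
#' @param threshold Legitimacy regime threshold (default 0.7).
#' @param window Rolling window length in steps (default 100).
#' @param stride Window stride in steps (default 10).
#' @return A `regime_variance` tibble: one row per window with `start`,
#'   `end`, `variance`, `mean_legitimacy`, `regime`; kernel density
#'   estimates of the two variance populations sit in the `densities`
#'   attribute and the one-sided rank test in [glance()].
#' @export
jacobian_variance_by_regime <- function(coeffs, table, threshold = 0.7,
                                        window = 100, stride = 10) {
  jac <- propaganda_jacobian(coeffs)
  leg <- table$Legitimacy[match(jac$time, table$time)]
  ok <- !is.na(jac$dActive_dPropaganda) & !is.na(leg)
  jac <- jac[ok, ]
  leg <- leg[ok]
  n <- nrow(jac)
  if (window > n) {
    abort_config(sprintf("window of %d steps exceeds the %d-step series", window, n))
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  res <- purrr::map_dfr(starts, function(s) {
    idx <- s:(s + window - 1L)
    tibble::tibble(
      start = jac$time[s], end = jac$time[s + window - 1L],
      variance = stats::var(jac$dActive_dPropaganda[idx]),
      mean_legitimacy = mean(leg[idx]))
  })
  res$regime <- ifelse(res$mean_legitimacy < threshold, "low", "high")
  class(res) <- c("regime_variance", class(res))
  attr(res, "threshold") <- threshold
  attr(res, "window") <- window
  attr(res, "stride") <- stride
  lowv <- res$variance[res$regime == "low"]
  highv <- res$variance[res$regime == "high"]
  dens <- list()
  if (length(lowv) >= 2 && stats::sd(lowv) > 0) dens$low <- stats::density(lowv)
  if (length(highv) >= 2 && stats::sd(highv) > 0) dens$high <- stats::density(highv)
  attr(res, "densities") <- dens
  res
}
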