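# Hyperparameter scans: prediction skill as a function of embedding
# dimension E and forecast horizon Tp, and kernel-width selection for the
# s-map.

#' The standard s-map kernel-width grid
#'
#' @return Numeric vector of candidate `theta` values from 0 (global linear)
#'   to 9 (strongly localized).
#' @export
default_theta_grid <- function() {
  c(0, 0.01, 0.1, 0.3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9)
}

scan_grid <- function(table, target, E_values, Tp_values, lib, pred, method,
                      theta) {
  if (any(E_values < 1) || any(E_values > 12)) {
    abort_config("embedding dimensions must lie in 1..12")
  }
  grid <- tidyr::expand_grid(E = as.integer(E_values), Tp = as.integer(Tp_values))
  grid$skill <- purrr::pmap_dbl(grid, function(E, Tp) {
    spec <- univariate_embedding(target, E = E, Tp = Tp)
    fc <- tryCatch(
      edm_predict(table, spec, lib = lib, pred = pred, method = method,
                  theta = theta),
      edmpc_empty_library = function(e) NULL,
      edmpc_insufficient_library = function(e) NULL)
    if (is.null(fc)) NA_real_ else fc$skill
  })
  grid
}

#' Scan prediction skill over embedding dimension
#'
#' For each embedding dimension `E` (univariate lag embedding of `target`
#' with 1-step lags `0:(E-1)`) and each horizon in `Tp_set`, computes the
#' out-of-sample forecast skill of `method` on the held-out `pred` rows. The
#' per-horizon "useful lower bound" on `E` is the smallest dimension whose
#' skill reaches `tol` (default 95%) of that horizon's maximum.
#'
#' @param table Observation tibble.
#' @param target Column to embed and predict.
#' @param E_range Embedding dimensions to scan (subset of 1..12).
#' @param Tp_set Forecast horizons to scan.
#' @param lib,pred Inclusive 1-based row ranges for library and prediction
#'   sets (must give non-empty portions).
#' @param method `"simplex"` (default) or `"smap"`.
#' @param theta S-map localization (ignored for simplex).
#' @param tol Saturation tolerance for the lower-bound rule.
#' @return An `edm_scan` tibble with columns `E`, `Tp`, `skill`; the
#'   saturation summary is available via [glance()] or
#'   [skill_saturation()].
#' @export
scan_embedding_dimension <- function(table, target, E_range = 1:10,
                                     Tp_set = 5L, lib, pred,
                                     method = c("simplex", "smap"), theta = 0,
                                     tol = 0.95) {
  method <- match.arg(method)
  lib <- check_range(lib, nrow(table), "lib")
  pred <- check_range(pred, nrow(table), "pred")
  grid <- scan_grid(table, target, E_range, Tp_set, lib, pred, method, theta)
  new_edm_scan(grid, along = "E", tol = tol)
}

#' Scan prediction skill over forecast horizon
#'
#' As [scan_embedding_dimension()] with the roles of `E` and `Tp` exchanged:
#' skill as a function of the forecast interval at fixed embedding
#' dimensions.
#'
#' @inheritParams scan_embedding_dimension
#' @param E_set Embedding dimensions to hold fixed.
#' @param Tp_range Forecast horizons to scan.
#' @return An `edm_scan` tibble with columns `E`, `Tp`, `skill`.
#' @export
scan_prediction_horizon <- function(table, target, E_set = 5L, Tp_range = 1:10,
                                    lib, pred, method = c("simplex", "smap"),
                                    theta = 0, tol = 0.95) {
  method <- match.arg(method)
  lib <- check_range(lib, nrow(table), "lib")
  pred <- check_range(pred, nrow(table), "pred")
  grid <- scan_grid(table, target, E_set, Tp_range, lib, pred, method, theta)
  new_edm_scan(grid, along = "Tp", tol = tol)
}

new_edm_scan <- function(grid, along, tol) {
  class(grid) <- c("edm_scan", class(grid))
  attr(grid, "along") <- along
  attr(grid, "tol") <- tol
  grid
}

#' Skill-saturation lower bound per horizon
#'
#' For each `Tp` in an embedding-dimension scan, the smallest `E` whose skill
#' is at least `tol` of the maximum skill over the scanned dimensions.
#'
#' @param scan An `edm_scan` from [scan_embedding_dimension()].
#' @param tol Fraction of the per-horizon maximum counted as saturated;
#'   defaults to the scan's own tolerance.
#' @return Tibble with columns `Tp`, `E_lower`, `max_skill`.
#' @export
skill_saturation <- function(scan, tol = NULL) {
  stopifnot(inherits(scan, "edm_scan"))
  tol <- tol %||% attr(scan, "tol")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(scan), .data$Tp),
    E_lower = {
      s <- .data$skill
      if (all(is.na(s))) NA_integer_ else {
        m <- max(s, na.rm = TRUE)
        .data$E[which(!is.na(s) & s >= tol * m)[1]]
      }
    },
    max_skill = if (all(is.na(.data$skill))) NA_real_ else
      max(.data$skill, na.rm = TRUE),
    .groups = "drop")
}

#' Select the s-map kernel width by out-of-sample skill
#'
#' Evaluates s-map forecast skill over a grid of `theta` values, predicting
#' the `pred` rows from a library built on the `lib` rows, and selects the
#' skill-maximizing value (ties resolved toward the smallest `theta`, i.e.
#' the most global map). To bound cost, at most `max_queries` evenly spaced
#' query rows are scored.
#'
#' @param table Observation tibble.
#' @param spec An [embedding_spec()].
#' @param theta_grid Candidate values, all `>= 0`.
#' @param lib,pred Inclusive 1-based row ranges.
#' @param max_queries Cap on the number of scored queries.
#' @return A `theta_selection`: list with `theta` (the chosen value) and
#'   `grid` (tibble of `theta`, `skill`).
#' @export
select_theta <- function(table, spec, theta_grid = default_theta_grid(),
                         lib, pred, max_queries = 300L) {
  if (length(theta_grid) == 0 || any(theta_grid < 0)) {
    abort_config("theta_grid must be a non-empty set of non-negative values")
  }
  theta_grid <- sort(theta_grid)
  L <- embed_table(table, spec, rows = lib)
  Q <- embed_table(table, spec, rows = pred)
  keep <- which(!is.na(Q$target_future))
  if (length(keep) > max_queries) {
    keep <- keep[unique(round(seq(1, length(keep), length.out = max_queries)))]
  }
  if (length(keep) < 3) {
    rlang::abort("too few scorable queries in the prediction range to select theta",
                 class = "edmpc_insufficient_library")
  }
  qX <- Q$rows[keep, , drop = FALSE]
  q_times <- Q$row_times[keep]
  obs <- Q$target_future[keep]
  skills <- vapply(theta_grid, function(th) {
    p <- edm_batch(L, qX, q_times, method = "smap", theta = th, k = NULL,
                   exclusion_radius = spec$Tp)
    pearson_skill(obs, p)
  }, numeric(1))
  if (all(is.na(skills))) {
    rlang::abort("forecast skill is undefined for every candidate theta",
                 class = "edmpc_insufficient_library")
  }
  best <- which.max(skills)  # first maximum = smallest theta on ties
  out <- list(theta = theta_grid[best],
              grid = tibble::tibble(theta = theta_grid, skill = skills))
  class(out) <- "theta_selection"
  out
}

#' @export
print.theta_selection <- function(x, ...) {
  cat(sprintf("<theta_selection> theta* = %g (skill %.4f over %d candidates)\n",
              x$theta, max(x$grid$skill, na.rm = TRUE), nrow(x$grid)))
  invisible(x)
}
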