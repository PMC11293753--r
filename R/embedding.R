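# Generalized state-space embedding: state vectors are built from backward
# lags of one or several observed columns, and each library row is paired
# with the value of the target column a fixed horizon Tp ahead.

#' Define a generalized embedding
#'
#' An embedding is an ordered list of (column, lag) coordinates, a target
#' column, and a prediction horizon `Tp`. Lags are backward (non-negative):
#' the state vector at time `t` is `(col_1(t - lag_1), ..., col_E(t - lag_E))`
#' and it is paired with `target(t + Tp)`.
#'
#' @param columns Character vector of column names.
#' @param lags Non-negative integer lags.
#' @param target Name of the predicted column.
#' @param Tp Prediction horizon in steps (`>= 1`).
#' @param cross When `TRUE` (default) the coordinates are the full
#'   column-by-lag grid; when `FALSE`, `columns` and `lags` are taken as
#'   parallel (column, lag) pairs.
#' @return An `embedding_spec` object; its `E` is the number of coordinates.
#' @export
#' @examples
#' embedding_spec(c("Quiet", "Jailed"), c(0, 2, 4), target = "Active", Tp = 5)
embedding_spec <- function(columns, lags, target, Tp = 1L, cross = TRUE) {
  grid <- if (cross) {
    tidyr::expand_grid(column = columns, lag = as.integer(lags))
  } else {
    tibble::tibble(column = columns, lag = as.integer(lags))
  }
  if (any(grid$lag < 0)) abort_config("lags must be non-negative (past/present only)")
  Tp <- as.integer(Tp)
  if (Tp < 1) abort_config("prediction horizon Tp must be >= 1")
  spec <- list(coords = grid, target = target, Tp = Tp, E = nrow(grid))
  class(spec) <- "embedding_spec"
  spec
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat(sprintf("<embedding_spec> E = %d, target = %s, Tp = %d\n  %s\n",
              x$E, x$target, x$Tp, paste(coord_labels(x), collapse = ", ")))
  invisible(x)
}

coord_labels <- function(spec) {
  ifelse(spec$coords$lag == 0,
         paste0(spec$coords$column, "(t)"),
         paste0(spec$coords$column, "(t-", spec$coords$lag, ")"))
}

#' The 6-dimensional Quiet/Jailed embedding used for Active forecasts
#'
#' Quiet and Jailed at backward lags 0, 2 and 4 (six coordinates, all from
#' past observations), predicting Active at horizon `Tp`.
#'
#' @param Tp Prediction horizon in steps.
#' @return An `embedding_spec`.
#' @export
generalized_embedding <- function(Tp = 5L) {
  embedding_spec(c("Quiet", "Jailed"), c(0L, 2L, 4L), target = "Active", Tp = Tp)
}

#' Univariate lag embedding of a single column
#'
#' Lags `0:(E-1)` of `target`, predicting the same column.
#'
#' @param target Column name.
#' @param E Embedding dimension.
#' @param Tp Prediction horizon in steps.
#' @return An `embedding_spec`.
#' @export
univariate_embedding <- function(target, E, Tp = 1L) {
  embedding_spec(target, 0:(E - 1), target = target, Tp = Tp)
}

#' The coefficient (Jacobian) embedding with a propaganda coordinate
#'
#' The Quiet/Jailed embedding of [generalized_embedding()] augmented with
#' Propaganda at lag 0; the s-map coefficient attached to the propaganda
#' coordinate estimates the time-varying partial derivative of Active with
#' respect to propaganda.
#'
#' @param Tp Prediction horizon in steps.
#' @return An `embedding_spec`.
#' @export
coefficient_embedding <- function(Tp = 5L) {
  spec <- embedding_spec(c("Quiet", "Jailed"), c(0L, 2L, 4L),
                         target = "Active", Tp = Tp)
  spec$coords <- dplyr::bind_rows(spec$coords,
                                  tibble::tibble(column = "Propaganda", lag = 0L))
  spec$E <- nrow(spec$coords)
  spec
}

#' Build a state-space library from a table
#'
#' Constructs one state vector per time step at which every (column, lag)
#' value exists and is non-missing, pairing each with the target value `Tp`
#' steps ahead (missing when beyond the table or the selected rows).
#'
#' @param table Observation tibble with a consecutive integer `time` column.
#' @param spec An [embedding_spec()].
#' @param rows Optional inclusive 1-based `(start, end)` row range; lags and
#'   target futures are taken from inside this range only, so rows outside it
#'   are never read.
#' @return A `state_library` with fields `rows` (matrix, one state vector per
#'   row), `row_times`, `target_future`, `k_N` (row count) and `spec`.
#' @export
#' @examples
#' tab <- make_fixture("logistic_map", 10)
#' embed_table(tab, univariate_embedding("x", E = 3, Tp = 1))
embed_table <- function(table, spec, rows = NULL) {
  stopifnot(inherits(spec, "embedding_spec"))
  needed <- unique(c(spec$coords$column, spec$target))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort_config(sprintf("column%s not found in table: %s",
                         if (length(missing_cols) > 1) "s" else "",
                         paste(missing_cols, collapse = ", ")))
  }
  if (!"time" %in% names(table)) abort_config("table must have a time column")
  if (!is.null(rows)) {
    rows <- check_range(rows, nrow(table), "rows")
    table <- table[rows[1]:rows[2], ]
  }
  n <- nrow(table)
  maxlag <- max(spec$coords$lag)
  if (n <= maxlag) {
    rlang::abort(sprintf(
      "table slice of %d rows is too short for maximum lag %d: no valid state vector",
      n, maxlag), class = "edmpc_empty_library")
  }
  idx <- (maxlag + 1):n
  X <- matrix(NA_real_, length(idx), spec$E,
              dimnames = list(NULL, coord_labels(spec)))
  for (j in seq_len(spec$E)) {
    X[, j] <- table[[spec$coords$column[j]]][idx - spec$coords$lag[j]]
  }
  keep <- stats::complete.cases(X)
  if (!any(keep)) {
    rlang::abort("no state vector is free of missing values",
                 class = "edmpc_empty_library")
  }
  X <- X[keep, , drop = FALSE]
  idx <- idx[keep]
  fut_idx <- idx + spec$Tp
  fut <- ifelse(fut_idx <= n, table[[spec$target]][pmin(fut_idx, n)], NA_real_)
  lib <- list(rows = X, row_times = table$time[idx], target_future = fut,
              k_N = nrow(X), spec = spec)
  class(lib) <- "state_library"
  lib
}

#' @export
print.state_library <- function(x, ...) {
  cat(sprintf("<state_library> %d state vectors (E = %d), %d with target futures; target %s, Tp = %d\n",
              x$k_N, x$spec$E, sum(!is.na(x$target_future)), x$spec$target,
              x$spec$Tp))
  invisible(x)
}
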