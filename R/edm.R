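# EDM prediction: simplex projection (nearest-neighbor weighted average) and
# the s-map (sequential locally weighted global linear map). Both operate on
# a state_library; the s-map's local linear coefficients double as
# time-varying interaction Jacobians.

#' Nearest neighbors of a query state
#'
#' Returns the `k` library rows closest to `y` in Euclidean distance,
#' distance-sorted with ties broken by earlier row time.
#'
#' @param lib A `state_library` from [embed_table()].
#' @param y Numeric query state vector of length `E`.
#' @param k Number of neighbors.
#' @param exclude_times Row times to exclude (e.g. near the query time when
#'   predicting in-library).
#' @param require_future When `TRUE`, only rows with a defined target future
#'   are candidates.
#' @return A `neighbor_set`: list with `indices` (into the library rows),
#'   `times`, `distances`, and `mean_distance`.
#' @export
nearest_neighbors <- function(lib, y, k, exclude_times = NULL,
                              require_future = FALSE) {
  stopifnot(inherits(lib, "state_library"))
  if (length(y) != ncol(lib$rows)) {
    abort_config(sprintf("query has %d coordinates but the library has E = %d",
                         length(y), ncol(lib$rows)))
  }
  cand <- seq_len(lib$k_N)
  if (!is.null(exclude_times)) cand <- cand[!(lib$row_times[cand] %in% exclude_times)]
  if (require_future) cand <- cand[!is.na(lib$target_future[cand])]
  if (k < 1 || k > length(cand)) {
    abort_config(sprintf("k = %d but only %d usable library rows", k, length(cand)))
  }
  d <- sqrt(colSums((t(lib$rows[cand, , drop = FALSE]) - as.numeric(y))^2))
  ord <- order(d, lib$row_times[cand])[seq_len(k)]
  sel <- cand[ord]
  out <- list(indices = sel, times = lib$row_times[sel], distances = d[ord],
              mean_distance = mean(d[ord]))
  class(out) <- "neighbor_set"
  out
}

#' Simplex projection forecast for one query
#'
#' The canonical nearest-neighbor projector: the prediction is the weighted
#' average of the target futures of the `k = E + 1` nearest library states,
#' with weights `exp(-d_i / d_1)` (`d_1` the nearest distance, floored at
#' machine epsilon when zero). The prediction always lies within the range of
#' the neighbor futures.
#'
#' @inheritParams nearest_neighbors
#' @param k Number of neighbors; defaults to `E + 1`.
#' @return The predicted target value (scalar).
#' @export
simplex_predict <- function(lib, y, k = NULL, exclude_times = NULL) {
  stopifnot(inherits(lib, "state_library"))
  if (is.null(k)) k <- ncol(lib$rows) + 1L
  nn <- tryCatch(
    nearest_neighbors(lib, y, k, exclude_times, require_future = TRUE),
    edmpc_config_error = function(e) {
      rlang::abort("not enough library rows with defined target futures",
                   class = "edmpc_insufficient_library", parent = e)
    })
  simplex_combine(nn$distances, lib$target_future[nn$indices])
}

simplex_combine <- function(d, futures) {
  d1 <- max(d[1], .Machine$double.eps)
  u <- exp(-d / d1)
  sum(u * futures) / sum(u)
}

#' S-map forecast and local linear coefficients for one query
#'
#' The sequential locally weighted global linear map: all usable library rows
#' enter a weighted least-squares regression of the target futures on the
#' state coordinates (plus intercept), with kernel weights
#' `w_i = exp(-theta * d_i / D)` where `D` is the mean neighbor distance.
#' `theta = 0` gives the global linear (uniformly weighted) map; larger
#' `theta` localizes the fit. The solution is the minimum-norm least-squares
#' solution via singular value decomposition (relative singular-value cutoff
#' `1e-10`), so rank-deficient designs (e.g. a constant coordinate) return a
#' solution rather than an error. The fitted coefficients are local partial
#' derivatives of the target with respect to each coordinate.
#'
#' @inheritParams nearest_neighbors
#' @param theta Kernel localization parameter, `>= 0`.
#' @return An `smap_solution`: list with `theta`, `weights`, `coefficients`
#'   (named, intercept first), and `prediction`.
#' @export
smap_predict <- function(lib, y, theta, exclude_times = NULL) {
  stopifnot(inherits(lib, "state_library"))
  if (theta < 0) abort_config("theta must be non-negative")
  usable <- which(!is.na(lib$target_future))
  if (!is.null(exclude_times)) {
    usable <- usable[!(lib$row_times[usable] %in% exclude_times)]
  }
  if (length(usable) == 0) {
    rlang::abort("no library row with a defined target future",
                 class = "edmpc_insufficient_library")
  }
  X <- lib$rows[usable, , drop = FALSE]
  d <- sqrt(colSums((t(X) - as.numeric(y))^2))
  D <- mean(d)
  w <- if (D > 0) exp(-theta * d / D) else rep(1, length(d))
  co <- smap_solve(X, lib$target_future[usable], w)
  out <- list(theta = theta, weights = w, coefficients = co,
              prediction = unname(co[1] + sum(co[-1] * as.numeric(y))))
  class(out) <- "smap_solution"
  out
}

# Weighted minimum-norm least squares of futures on [1 | X].
smap_solve <- function(X, b, w) {
  A <- cbind(1, X) * w
  co <- lstsq_minnorm(A, b * w)
  labels <- colnames(X) %||% paste0("c", seq_len(ncol(X)))
  names(co) <- c("(Intercept)", labels)
  co
}

# Minimum-norm least-squares solution via SVD with relative singular-value
# cutoff; rank-deficient designs are handled without error.
lstsq_minnorm <- function(A, b, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  if (!any(keep)) return(rep(0, ncol(A)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' @export
print.smap_solution <- function(x, ...) {
  cat(sprintf("<smap_solution> theta = %g, prediction = %.6g\n", x$theta,
              x$prediction))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Pearson forecast skill
#'
#' Sample Pearson correlation between observed and predicted values over the
#' pairs where both are finite. With fewer than three valid pairs, or zero
#' variance in either argument, the skill is undefined and `NA` is returned
#' (a sentinel, not an error), so hyperparameter scans can contain degenerate
#' cells.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Pearson correlation in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' pearson_skill(1:10, (1:10) * 2 + 3)
pearson_skill <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) return(NA_real_)
  o <- observed[ok]; p <- predicted[ok]
  if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
  stats::cor(o, p)
}

#' Out-of-sample EDM forecast over a table
#'
#' Builds the state-space library from `lib` rows, forms query states from
#' `pred` rows, and predicts the target `Tp` steps ahead of every query with
#' either simplex projection or the s-map. Library rows whose time stamps lie
#' within `exclusion_radius` steps of a query time are excluded for that
#' query, which prevents trivial self-matching under serial correlation when
#' the two ranges overlap (in-sample scans); for disjoint ranges it has no
#' effect.
#'
#' @param table Observation tibble.
#' @param spec An [embedding_spec()].
#' @param lib,pred Inclusive 1-based `(start, end)` row ranges for the
#'   library and the prediction (query) set.
#' @param method `"simplex"` or `"smap"`.
#' @param theta S-map localization parameter (ignored for simplex).
#' @param k Simplex neighbor count; defaults to `E + 1`.
#' @param exclusion_radius Temporal exclusion radius in steps; defaults to
#'   `spec$Tp`.
#' @return An `edm_forecast`: aligned (time, observed, predicted) pairs, the
#'   Pearson skill over complete pairs, and the forecast parameters.
#' @export
#' @examples
#' tab <- make_fixture("logistic_map", 200)
#' fc <- edm_predict(tab, univariate_embedding("x", E = 2, Tp = 1),
#'                   lib = c(1, 100), pred = c(101, 200))
#' glance(fc)
edm_predict <- function(table, spec, lib, pred, method = c("simplex", "smap"),
                        theta = 0, k = NULL, exclusion_radius = NULL) {
  method <- match.arg(method)
  L <- embed_table(table, spec, rows = lib)
  Q <- embed_table(table, spec, rows = pred)
  if (is.null(exclusion_radius)) exclusion_radius <- spec$Tp
  pred_vals <- edm_batch(L, Q$rows, Q$row_times, method = method, theta = theta,
                         k = k, exclusion_radius = exclusion_radius)
  pairs <- tibble::tibble(
    time = Q$row_times + spec$Tp,
    observed = Q$target_future,
    predicted = pred_vals)
  out <- list(pairs = pairs,
              skill = pearson_skill(pairs$observed, pairs$predicted),
              Tp = spec$Tp, method = method,
              theta = if (method == "smap") theta else NA_real_,
              k = if (method == "simplex") (k %||% (spec$E + 1L)) else NA_integer_,
              spec = spec)
  class(out) <- "edm_forecast"
  out
}

#' @export
print.edm_forecast <- function(x, ...) {
  cat(sprintf("<edm_forecast> %s, Tp = %d, %d predictions (%d scored), skill rho = %.4f\n",
              x$method, x$Tp, nrow(x$pairs),
              sum(is.finite(x$pairs$observed) & is.finite(x$pairs$predicted)),
              x$skill))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Batch prediction of many queries against one library. Distances are
# computed as one matrix product; each query then applies its own temporal
# exclusion mask.
edm_batch <- function(L, qX, q_times, method, theta, k, exclusion_radius) {
  usable <- which(!is.na(L$target_future))
  if (length(usable) == 0) {
    rlang::abort("no library row with a defined target future",
                 class = "edmpc_insufficient_library")
  }
  X <- L$rows[usable, , drop = FALSE]
  fut <- L$target_future[usable]
  times <- L$row_times[usable]
  if (is.null(k)) k <- ncol(X) + 1L
  d2 <- outer(rowSums(qX^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(qX)), rowSums(X^2)) - 2 * tcrossprod(qX, X)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  n_q <- nrow(qX)
  preds <- rep(NA_real_, n_q)
  for (i in seq_len(n_q)) {
    keep <- abs(times - q_times[i]) > exclusion_radius
    if (!any(keep)) next
    d <- dmat[i, keep]
    if (method == "simplex") {
      if (sum(keep) < k) next
      ord <- order(d, times[keep])[seq_len(k)]
      preds[i] <- simplex_combine(d[ord], fut[keep][ord])
    } else {
      D <- mean(d)
      w <- if (D > 0) exp(-theta * d / D) else rep(1, length(d))
      co <- smap_solve(X[keep, , drop = FALSE], fut[keep], w)
      preds[i] <- co[1] + sum(co[-1] * qX[i, ])
    }
  }
  preds
}
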