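# Time-varying interaction strengths: repeated s-map solutions along a run
# yield one coefficient vector per predictable time step; the coefficient
# attached to the Propaganda coordinate estimates the time-varying partial
# derivative of Active with respect to propaganda.

#' S-map coefficient (Jacobian) series along a table
#'
#' Solves the s-map at every library row of `table` (in-sample queries with a
#' temporal exclusion radius) and records the full local linear coefficient
#' vector. Coordinates whose library column is (numerically) constant are
#' collinear with the intercept; the minimum-norm solution is still returned
#' and such coordinates are flagged in the `unreliable` attribute.
#'
#' @param table Observation tibble.
#' @param spec An [embedding_spec()]; for the propaganda Jacobian use
#'   [coefficient_embedding()], which includes Propaganda at lag 0.
#' @param theta S-map localization parameter.
#' @param rows Optional inclusive 1-based row range to restrict the library.
#' @param exclusion_radius Temporal exclusion radius; defaults to `spec$Tp`.
#' @return A `coefficient_series` tibble: `time` plus one column per
#'   coefficient (intercept first), one row per predictable time step.
#' @export
coefficient_series <- function(table, spec = coefficient_embedding(), theta = 2,
                               rows = NULL, exclusion_radius = NULL) {
  L <- embed_table(table, spec, rows = rows)
  usable <- which(!is.na(L$target_future))
  if (length(usable) < spec$E + 2) {
    rlang::abort("too few library rows with target futures for a coefficient series",
                 class = "edmpc_insufficient_library")
  }
  if (is.null(exclusion_radius)) exclusion_radius <- spec$Tp
  X <- L$rows[usable, , drop = FALSE]
  fut <- L$target_future[usable]
  times <- L$row_times[usable]
  col_sd <- apply(X, 2, stats::sd)
  unreliable <- colnames(X)[col_sd < 1e-12]
  n <- length(usable)
  co_mat <- matrix(NA_real_, n, spec$E + 1,
                   dimnames = list(NULL, c("(Intercept)", colnames(X))))
  for (i in seq_len(n)) {
    keep <- abs(times - times[i]) > exclusion_radius
    if (sum(keep) < spec$E + 2) next
    d <- sqrt(colSums((t(X[keep, , drop = FALSE]) - X[i, ])^2))
    D <- mean(d)
    w <- if (D > 0) exp(-theta * d / D) else rep(1, length(d))
    co_mat[i, ] <- smap_solve(X[keep, , drop = FALSE], fut[keep], w)
  }
  out <- tibble::as_tibble(as.data.frame(co_mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  class(out) <- c("coefficient_series", class(out))
  attr(out, "theta") <- theta
  attr(out, "spec") <- spec
  attr(out, "unreliable") <- unreliable
  if (length(unreliable) > 0) {
    rlang::warn(sprintf(
      "constant coordinate%s collinear with the intercept; coefficient%s unreliable: %s",
      if (length(unreliable) > 1) "s" else "",
      if (length(unreliable) > 1) "s" else "",
      paste(unreliable, collapse = ", ")))
  }
  out
}

#' Extract the propaganda Jacobian from a coefficient series
#'
#' @param coeffs A `coefficient_series` whose spec includes Propaganda at
#'   lag 0.
#' @return Tibble with columns `time` and `dActive_dPropaganda`.
#' @export
propaganda_jacobian <- function(coeffs) {
  stopifnot(inherits(coeffs, "coefficient_series"))
  col <- "Propaganda(t)"
  if (!col %in% names(coeffs)) {
    abort_config("coefficient series has no Propaganda(t) coordinate")
  }
  tibble::tibble(time = coeffs$time, dActive_dPropaganda = coeffs[[col]])
}
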