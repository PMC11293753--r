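# Deterministic synthetic series for unit-level oracles: chaotic logistic
# map, AR(1), constants, and a linear-forcing table for coefficient-recovery
# tests.

#' Generate a deterministic test fixture series
#'
#' Four generators are available:
#' * `"logistic_map"`: the chaotic map `x[t+1] = r * x[t] * (1 - x[t])`
#'   (parameters `r`, `x0`); fully deterministic.
#' * `"ar1"`: `x[t+1] = phi * x[t] + e[t]`, `e ~ N(0, sd^2)` (parameters
#'   `phi`, `sd`, `x0`); with `sd = 0` the closed-form geometric decay.
#' * `"constant"`: a constant series (parameter `value`).
#' * `"linear_forcing"`: a full observation table in which
#'   `Active[t] = a * Propaganda[t - horizon] + b * Quiet[t - horizon] + noise`
#'   with i.i.d. uniform Propaganda and integer Quiet; the known coefficients
#'   `a` and `b` make s-map coefficient recovery checkable.
#'
#' @param generator One of `"logistic_map"`, `"ar1"`, `"constant"`,
#'   `"linear_forcing"`.
#' @param length Number of time steps.
#' @param seed Optional integer seed (identical spec implies identical series).
#' @param ... Generator parameters as described above.
#' @return A tibble with a `time` column and either a single series `x` or,
#'   for `"linear_forcing"`, the full observation schema.
#' @export
#' @examples
#' make_fixture("logistic_map", 5)
#' make_fixture("ar1", 4, phi = 0.5, sd = 0, x0 = 1)
make_fixture <- function(generator, length, seed = NULL, ...) {
  length <- as.integer(length)
  if (length < 1) abort_config("fixture length must be positive")
  if (!is.null(seed)) set.seed(seed)
  dots <- list(...)
  grab <- function(name, default) if (name %in% names(dots)) dots[[name]] else default
  tm <- seq_len(length)
  switch(
    generator,
    logistic_map = {
      r <- grab("r", 3.9); x0 <- grab("x0", 0.2)
      x <- numeric(length)
      x[1] <- x0
      for (i in seq_len(length - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
      tibble::tibble(time = tm, x = x)
    },
    ar1 = {
      phi <- grab("phi", 0.5); sd <- grab("sd", 1); x0 <- grab("x0", 0)
      eps <- if (sd > 0) stats::rnorm(length, sd = sd) else numeric(length)
      x <- numeric(length)
      x[1] <- x0
      for (i in seq_len(length - 1)) x[i + 1] <- phi * x[i] + eps[i]
      tibble::tibble(time = tm, x = x)
    },
    constant = {
      tibble::tibble(time = tm, x = rep(grab("value", 1), length))
    },
    linear_forcing = {
      a <- grab("a", 2); b <- grab("b", 0.5)
      noise_sd <- grab("noise_sd", 0.1); horizon <- as.integer(grab("horizon", 1))
      if (horizon < 0 || horizon >= length) {
        abort_config("linear_forcing horizon must lie in [0, length)")
      }
      propaganda <- stats::runif(length)
      quiet <- sample(400:800, length, replace = TRUE)
      active <- rep(NA_real_, length)
      idx <- (horizon + 1):length
      active[idx] <- a * propaganda[idx - horizon] + b * quiet[idx - horizon] +
        stats::rnorm(base::length(idx), sd = noise_sd)
      tibble::tibble(time = tm, Quiet = as.numeric(quiet), Active = active,
                     Jailed = 0, Legitimacy = 0.75, Propaganda = propaganda)
    },
    abort_config(sprintf("unknown fixture generator '%s'", generator))
  )
}
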