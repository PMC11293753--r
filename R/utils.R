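# Shared helpers: error classes, seed derivation, range handling.

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "edmpc_config_error", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "edmpc_format_error", ...)
}

#' Derive a labeled sub-seed from a root seed
#'
#' A single root seed drives a whole run; independent module substreams
#' (legitimacy schedule, agent initialization, simulation) get their own
#' integer seeds derived deterministically from the root seed and a label.
#' This keeps, e.g., the sampled legitimacy schedule identical between a
#' controlled run and its uncontrolled twin.
#'
#' @param seed Integer root seed.
#' @param label Character stream label, e.g. `"schedule"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "schedule")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  code <- utf8ToInt(label)
  h <- sum(code * seq_along(code))
  as.integer(1 + (abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483645)
}

# Inclusive 1-based (start, end) row range, validated against a table length.
check_range <- function(range, n, what = "range") {
  if (!is.numeric(range) || length(range) != 2 || anyNA(range)) {
    abort_config(sprintf("%s must be a numeric (start, end) pair", what))
  }
  range <- as.integer(range)
  if (range[1] < 1 || range[2] > n || range[1] > range[2]) {
    abort_config(sprintf("%s (%d, %d) is not a valid 1-based row range for %d rows",
                         what, range[1], range[2], n))
  }
  range
}

# Parse "a:b" into c(a, b) (CLI surface).
parse_range <- function(x) {
  parts <- suppressWarnings(as.integer(strsplit(x, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || anyNA(parts)) {
    abort_config(sprintf("cannot parse '%s' as a row range 'start:end'", x))
  }
  parts
}
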