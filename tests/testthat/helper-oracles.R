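# Independent brute-force oracles, deliberately naive implementations that
# share no code with the package internals.

# Exhaustive nearest neighbors: full distance sort with time tie-break.
brute_nn <- function(rows, times, y, k) {
  d <- apply(rows, 1, function(r) sqrt(sum((r - y)^2)))
  ord <- order(d, times)
  list(indices = ord[seq_len(k)], distances = d[ord[seq_len(k)]])
}

# Naive simplex projection (loops, no shared helpers).
brute_simplex <- function(rows, times, futures, y, k, exclude_times = integer()) {
  ok <- which(!is.na(futures) & !(times %in% exclude_times))
  d <- numeric(length(ok))
  for (i in seq_along(ok)) d[i] <- sqrt(sum((rows[ok[i], ] - y)^2))
  ord <- order(d, times[ok])[seq_len(k)]
  dd <- d[ord]
  d1 <- max(dd[1], .Machine$double.eps)
  u <- exp(-dd / d1)
  sum(u * futures[ok][ord]) / sum(u)
}

# Textbook Pearson correlation from raw sums.
textbook_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Direct-iteration logistic map oracle.
iterate_logistic <- function(r, x0, n) {
  x <- numeric(n)
  x[1] <- x0
  for (i in seq_len(n - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
  x
}

# Brute-force enumeration of valid embedding rows: for 1-based time t over a
# table of n rows, a prediction row needs every lag available and the target
# future inside the table.
brute_valid_rows <- function(n, lags, Tp) {
  sum(vapply(seq_len(n), function(t) all(t - lags >= 1) && t + Tp <= n, logical(1)))
}
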