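make_lib <- function(rows, futures = NULL, times = NULL) {
  rows <- as.matrix(rows)
  if (is.null(times)) times <- seq_len(nrow(rows))
  if (is.null(futures)) futures <- rep(NA_real_, nrow(rows))
  lib <- list(rows = rows,
              row_times = times,
              target_future = futures,
              k_N = nrow(rows),
              spec = embedding_spec("x", seq_len(ncol(rows)) - 1, target = "x",
                                    Tp = 1, cross = FALSE))
  class(lib) <- "state_library"
  lib
}

test_that("nearest neighbors match the worked example and brute force", {
  lib <- make_lib(rbind(c(0, 0), c(1, 1), c(2, 2)), futures = c(1, 2, 3))
  nn <- nearest_neighbors(lib, c(0.9, 0.9), k = 2)
  expect_equal(nn$indices, c(2L, 1L))
  expect_equal(nn$distances, c(sqrt(0.02), sqrt(1.62)), tolerance = 1e-12)
  expect_equal(nn$mean_distance, mean(nn$distances))

  # identity: query equal to a library row
  nn0 <- nearest_neighbors(lib, c(1, 1), k = 1)
  expect_equal(nn0$indices, 2L)
  expect_equal(nn0$distances, 0)

  # equidistant rows resolve in time order
  sq <- make_lib(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  tie <- nearest_neighbors(sq, c(0, 0), k = 4)
  expect_equal(tie$indices, 1:4)
})

test_that("nearest neighbors equal exhaustive sort on random libraries", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    E <- sample(1:6, 1)
    rows <- matrix(rnorm(n * E), n, E)
    lib <- make_lib(rows)
    y <- rnorm(E)
    for (k in unique(c(1, sample(n, 2), n))) {
      got <- nearest_neighbors(lib, y, k)
      want <- brute_nn(rows, seq_len(n), y, k)
      expect_equal(got$indices, want$indices)
      expect_equal(got$distances, want$distances, tolerance = 1e-12)
    }
  }
  expect_error(nearest_neighbors(make_lib(diag(2)), c(0, 0), k = 3),
               class = "edmpc_config_error")
})

test_that("simplex: identical futures, coincident query, and bounds", {
  lib <- make_lib(matrix(rnorm(12), 6, 2), futures = rep(7, 6))
  expect_equal(simplex_predict(lib, c(0, 0)), 7)

  # coincident row dominates under the epsilon-floor convention
  rows <- rbind(c(0, 0), c(3, 3), c(4, 4), c(5, 5))
  lib2 <- make_lib(rows, futures = c(10, 20, 30, 40))
  p <- simplex_predict(lib2, c(0, 0), k = 3)
  expect_equal(p, 10, tolerance = 1e-6)
  expect_equal(p, brute_simplex(rows, 1:4, c(10, 20, 30, 40), c(0, 0), 3))

  set.seed(3)
  for (rep in 1:20) {
    rows <- matrix(rnorm(20), 10, 2)
    fut <- rnorm(10)
    lib3 <- make_lib(rows, futures = fut)
    y <- rnorm(2)
    p <- simplex_predict(lib3, y)
    nnf <- brute_nn(rows, 1:10, y, 3)
    expect_gte(p, min(fut[nnf$indices]))
    expect_lte(p, max(fut[nnf$indices]))
    expect_equal(p, brute_simplex(rows, 1:10, fut, y, 3), tolerance = 1e-12)
  }
})

test_that("simplex leave-one-out skill on the chaotic logistic map exceeds 0.99", {
  tab <- make_fixture("logistic_map", 300)
  fc <- edm_predict(tab, univariate_embedding("x", E = 2, Tp = 1),
                    lib = c(1, 300), pred = c(1, 300))
  expect_gt(fc$skill, 0.99)
  # cross-check a handful of predictions against the naive oracle
  lib <- embed_table(tab, univariate_embedding("x", E = 2, Tp = 1))
  for (i in c(5, 50, 200)) {
    y <- lib$rows[i, ]
    tq <- lib$row_times[i]
    excl <- lib$row_times[abs(lib$row_times - tq) <= 1]
    expect_equal(fc$pairs$predicted[i],
                 brute_simplex(lib$rows, lib$row_times, lib$target_future,
                               y, 3, exclude_times = excl),
                 tolerance = 1e-10)
  }
})

test_that("s-map at theta = 0 recovers an exact linear rule and matches lm()", {
  set.seed(8)
  n <- 80
  x <- runif(n)
  tab <- tibble::tibble(time = 1:n, x = x,
                        z = c(NA, 0.5 * x[1:(n - 1)] + 0.1))
  lib <- embed_table(tab, embedding_spec("x", 0, target = "z", Tp = 1))
  # embed pairs x(t) with z(t+1) = 0.5 x(t) + 0.1
  s <- smap_predict(lib, y = 0.3, theta = 0)
  expect_equal(unname(s$coefficients), c(0.1, 0.5), tolerance = 1e-10)
  expect_equal(s$prediction, 0.25, tolerance = 1e-10)

  # theta = 0 equals ordinary least squares on a noisy multivariate design
  X <- matrix(rnorm(300), 100, 3)
  b <- X %*% c(1, -2, 0.5) + rnorm(100, sd = 0.3)
  lib2 <- make_lib(X, futures = as.numeric(b))
  s2 <- smap_predict(lib2, y = c(0, 0, 0), theta = 0)
  ols <- stats::lm(b ~ X)
  expect_equal(unname(s2$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-8)
})

test_that("s-map weights follow the exponential kernel exactly", {
  # a neighbor at distance equal to the mean distance gets weight exp(-theta)
  rows <- rbind(1, 3)   # query 2: distances 1 and 1, D = 1
  lib <- make_lib(rows, futures = c(5, 6))
  for (th in c(0, 0.5, 2, 9)) {
    s <- smap_predict(lib, y = 2, theta = th)
    expect_equal(unname(s$weights), rep(exp(-th), 2), tolerance = 1e-12)
  }
  # theta = 0 gives unit weights regardless of distance
  lib2 <- make_lib(matrix(rnorm(20), 10, 2), futures = rnorm(10))
  s0 <- smap_predict(lib2, y = c(5, 5), theta = 0)
  expect_true(all(s0$weights == 1))
})

test_that("s-map weight monotonicity in distance and theta", {
  set.seed(4)
  lib <- make_lib(matrix(runif(40), 20, 2), futures = rnorm(20))
  y <- c(0.5, 0.5)
  d <- sqrt(colSums((t(lib$rows) - y)^2))
  for (th in c(0.5, 1, 3)) {
    s <- smap_predict(lib, y, theta = th)
    expect_true(all(diff(s$weights[order(d)]) <= 1e-12))
  }
  w1 <- smap_predict(lib, y, theta = 1)$weights
  w2 <- smap_predict(lib, y, theta = 2)$weights
  off <- d > min(d)  # strictly decreasing in theta wherever d > 0
  expect_true(all(w2[off] < w1[off]))
})

test_that("s-map degenerate designs: constant library and rank deficiency", {
  lib <- make_lib(matrix(2, 8, 2), futures = rep(4.5, 8))
  s <- smap_predict(lib, y = c(2, 2), theta = 1.5)  # D = 0 branch
  expect_equal(s$prediction, 4.5, tolerance = 1e-9)

  # duplicated coordinate: rank-deficient, still solvable
  x <- rnorm(30)
  lib2 <- make_lib(cbind(x, x), futures = 2 * x + 1)
  s2 <- smap_predict(lib2, y = c(0.4, 0.4), theta = 0)
  expect_equal(s2$prediction, 2 * 0.4 + 1, tolerance = 1e-8)
})

test_that("large theta drives in-sample error to zero on a noiseless map", {
  tab <- make_fixture("logistic_map", 250)
  spec <- univariate_embedding("x", E = 2, Tp = 1)
  errs <- vapply(c(0, 1, 2, 5, 10), function(th) {
    fc <- edm_predict(tab, spec, lib = c(1, 250), pred = c(1, 250),
                      method = "smap", theta = th)
    sqrt(mean((fc$pairs$observed - fc$pairs$predicted)^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))  # monotone non-increasing trend
  expect_lt(errs[5], errs[1] / 10)
})

test_that("pearson skill: identities, hand-computed value, sentinels, affine invariance", {
  expect_equal(pearson_skill(1:10, 1:10), 1)
  expect_equal(pearson_skill(1:10, -(1:10)), -1)
  o <- c(1, 2, 3, 4); p <- c(2, 2.5, 4, 4.5)
  expect_equal(pearson_skill(o, p), textbook_pearson(o, p), tolerance = 1e-12)
  expect_true(is.na(pearson_skill(c(1, 2), c(1, 2))))
  expect_true(is.na(pearson_skill(rep(1, 5), 1:5)))
  expect_equal(pearson_skill(c(1, NA, 3, 4, 5), c(2, 9, 4, 5, 7)),
               pearson_skill(c(1, 3, 4, 5), c(2, 4, 5, 7)))
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_skill(2 * a + 3, b), pearson_skill(a, b), tolerance = 1e-12)
  expect_equal(pearson_skill(a, 0.1 * b - 7), pearson_skill(a, b), tolerance = 1e-12)
})
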