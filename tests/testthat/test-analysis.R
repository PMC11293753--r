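pulse_table <- function(active) {
  n <- length(active)
  tibble::tibble(time = seq_len(n), Quiet = 1200 - active, Active = active,
                 Jailed = 0, Legitimacy = 0.8, Propaganda = 0.1)
}

test_that("episode detection: empty, single pulse, merging, idempotence", {
  expect_equal(nrow(detect_episodes(pulse_table(rep(0, 100)))), 0L)

  a <- rep(0, 100); a[31:40] <- 120
  ep <- detect_episodes(pulse_table(a))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start, 31)
  expect_equal(ep$end, 40)
  expect_equal(ep$peak, 120)

  # two pulses 10 steps apart merge at min_gap = 20, stay separate at 5
  b <- rep(0, 200); b[51:60] <- 100; b[71:80] <- 90
  expect_equal(nrow(detect_episodes(pulse_table(b), min_gap = 20)), 1L)
  two <- detect_episodes(pulse_table(b), min_gap = 5)
  expect_equal(nrow(two), 2L)
  expect_equal(attr(two, "waiting_times"), 20)

  # appending sub-threshold steps changes nothing
  longer <- detect_episodes(pulse_table(c(b, rep(0, 50))), min_gap = 5)
  expect_equal(as.data.frame(longer), as.data.frame(two))
})

test_that("trapped-state detection honors threshold and duration", {
  a <- rep(600, 300)
  r <- detect_trapped_state(pulse_table(a))
  expect_true(r$trapped)
  expect_equal(r$onset, 1L)

  short <- rep(0, 400); short[101:250] <- 600   # 150 < 200 steps
  expect_false(detect_trapped_state(pulse_table(short))$trapped)
  # but a lower duration requirement catches it
  expect_true(detect_trapped_state(pulse_table(short), duration = 100)$trapped)
})

test_that("skill protocol is exact on linearly generated data and near zero on shuffled targets", {
  tab <- exact_linear_table()
  fc <- skill_protocol(tab, train = c(1, 300), test = c(351, 600))
  expect_gt(fc$skill, 0.999)

  set.seed(17)
  shuffled <- tab
  shuffled$Active <- sample(shuffled$Active)
  fc2 <- skill_protocol(shuffled, train = c(1, 300), test = c(351, 600))
  expect_lt(abs(fc2$skill), 0.25)

  expect_error(skill_protocol(tab, train = c(1, 300), test = c(200, 500)),
               class = "edmpc_config_error")
})

test_that("test rows are never read during library construction or theta selection", {
  tab <- exact_linear_table()
  spec <- generalized_embedding(Tp = 5)
  lib <- embed_table(tab, spec, rows = c(1, 300))
  sel <- select_theta(tab, spec, lib = c(1, 200), pred = c(201, 300))
  poisoned <- tab
  poisoned$Active[351:600] <- 1e8
  poisoned$Quiet[351:600] <- -1e8
  lib2 <- embed_table(poisoned, spec, rows = c(1, 300))
  sel2 <- select_theta(poisoned, spec, lib = c(1, 200), pred = c(201, 300))
  expect_identical(lib$rows, lib2$rows)
  expect_identical(lib$target_future, lib2$target_future)
  expect_equal(sel$theta, sel2$theta)
  expect_equal(sel$grid, sel2$grid)
})

test_that("regime variance: zero-variance coefficients, scaling oracle, tie rule", {
  # synthetic coefficient series: noise sd tripled below the threshold
  set.seed(23)
  n <- 1200
  leg <- rep(c(0.65, 0.8), each = n / 2)
  coef <- stats::rnorm(n, sd = ifelse(leg < 0.7, 3, 1))
  cs <- tibble::tibble(time = seq_len(n), `(Intercept)` = 0,
                       `Propaganda(t)` = coef)
  class(cs) <- c("coefficient_series", class(cs))
  tab <- tibble::tibble(time = seq_len(n), Legitimacy = leg)
  rv <- jacobian_variance_by_regime(cs, tab, window = 100, stride = 10)
  g <- glance(rv)
  ratio <- g$median_low / g$median_high
  expect_gt(ratio, 6)
  expect_lt(ratio, 13.5)
  expect_lt(g$rank_p_value, 1e-6)
  # every window labeled exactly once
  expect_equal(nrow(rv), length(seq(1, n - 100 + 1, by = 10)))

  # constant coefficients give zero variance in both regimes
  cs0 <- cs; cs0$`Propaganda(t)` <- 1.5
  rv0 <- jacobian_variance_by_regime(cs0, tab, window = 100, stride = 10)
  expect_true(all(rv0$variance == 0))

  # mean legitimacy exactly at the threshold goes to the high regime
  cs1 <- cs[1:200, ]
  tab1 <- tibble::tibble(time = 1:200, Legitimacy = 0.7)
  rv1 <- jacobian_variance_by_regime(cs1, tab1, window = 100, stride = 50)
  expect_true(all(rv1$regime == "high"))

  expect_error(jacobian_variance_by_regime(cs1, tab1, window = 500),
               class = "edmpc_config_error")
})
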