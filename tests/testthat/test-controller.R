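test_that("logistic law: midpoint, asymptotes, bounds, monotonicity", {
  expect_equal(propaganda_response(50), 0.06 + 0.54 / 2, tolerance = 1e-12)
  expect_equal(propaganda_response(1e9), 0.6, tolerance = 1e-9)
  expect_equal(propaganda_response(-1e9), 0.06, tolerance = 1e-9)
  A <- seq(-200, 400, by = 2.5)   # central range: strict bounds and slope
  P <- propaganda_response(A)
  expect_true(all(P > 0.06 & P < 0.6))
  expect_true(all(diff(P) > 0))
  wide <- propaganda_response(seq(-5000, 5000, by = 50))  # saturated tails
  expect_true(all(wide >= 0.06 - 1e-12 & wide <= 0.6 + 1e-12))
  expect_true(all(diff(wide) >= 0))
})

test_that("logistic response obeys its Lipschitz slope bound", {
  prm <- controller_params()
  A <- seq(-200, 400, by = 1)
  P <- propaganda_response(A, prm)
  bound <- (prm$P_max - prm$P_min) * prm$m * diff(A) / 4
  expect_true(all(abs(diff(P)) <= bound + 1e-12))
})

test_that("parameter and configuration validation", {
  expect_error(controller_params(P_min = 0.5, P_max = 0.5),
               class = "edmpc_config_error")
  expect_error(controller_params(m = 0), class = "edmpc_config_error")
  expect_error(control_config(warmup_obs = 3), class = "edmpc_config_error")
})

test_that("control never engages when warm-up exceeds the run length", {
  loop <- control_config(warmup_obs = 100)
  con <- run_scenario(scenario_config(seed = 9, scenario = "controlled",
                                      run_length = 50, params = small_params(),
                                      schedule = "random", loop = loop))
  unc <- run_scenario(scenario_config(seed = 9, scenario = "uncontrolled",
                                      run_length = 50, params = small_params(),
                                      schedule = "random"))
  expect_equal(as.data.frame(con)[ts_cols <- names(unc)],
               as.data.frame(unc)[ts_cols])
  expect_true(is.na(attr(con, "engaged_at")))
})

test_that("a pinched controller reproduces a constant-propaganda run", {
  pinched <- controller_params(P_min = 0.1, P_max = 0.1 + 1e-9)
  loop <- control_config(warmup_obs = 20)
  # warm-up of 20 steps leaves too few scorable rows at first: the loop defers
  # theta selection with a warning and holds propaganda, which is the contract
  suppressWarnings(
    con <- run_scenario(scenario_config(seed = 13, scenario = "controlled",
                                        run_length = 60, params = small_params(),
                                        schedule = "random", propaganda = 0.1,
                                        controller = pinched, loop = loop)))
  unc <- run_scenario(scenario_config(seed = 13, scenario = "uncontrolled",
                                      run_length = 60, params = small_params(),
                                      schedule = "random", propaganda = 0.1))
  expect_equal(con$Quiet, unc$Quiet, tolerance = 1e-12)
  expect_equal(con$Active, unc$Active, tolerance = 1e-12)
  expect_equal(con$Jailed, unc$Jailed, tolerance = 1e-12)
})

test_that("the first controller estimate lands exactly after the warm-up", {
  loop <- control_config(warmup_obs = 40)
  con <- run_scenario(scenario_config(seed = 9, scenario = "controlled",
                                      run_length = 60, params = small_params(),
                                      schedule = "random", loop = loop))
  expect_equal(attr(con, "engaged_at"), 41L)
  expect_true(all(con$Propaganda[1:40] == 0.1))
  expect_false(con$Propaganda[41] == 0.1)
  expect_true(all(con$Propaganda[41:60] > 0.06 & con$Propaganda[41:60] < 0.6))
  expect_false(is.na(attr(con, "theta")))
})
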