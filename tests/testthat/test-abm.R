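test_that("initialization: all Quiet, valid draws, determinism, capacity bound", {
  w <- init_rebellion(rebellion_params(), seed = 2)
  cnt <- world_counts(w)
  expect_equal(unname(cnt), c(1200L, 0L, 0L))
  expect_true(all(w$risk_aversion >= 0 & w$risk_aversion <= 1))
  expect_true(all(w$perceived_hardship >= 0 & w$perceived_hardship <= 1))
  expect_equal(sum(w$occupancy > 0), 1200 + 64)
  expect_equal(sort(c(w$citizen_pos, w$cop_pos)), sort(which(w$occupancy > 0)))

  w2 <- init_rebellion(rebellion_params(), seed = 2)
  expect_identical(w, w2)

  expect_error(rebellion_params(n_citizens = 1600, n_cops = 1),
               class = "edmpc_config_error")
})

test_that("grievance and arrest probability formulas", {
  expect_equal(grievance(1, 1), 0)
  expect_equal(grievance(0.5, 0.7), 0.15)
  expect_equal(grievance(1, 0), 1)
  expect_equal(arrest_probability(0, log(10)), 0)
  expect_equal(arrest_probability(1, log(10)), 0.9, tolerance = 1e-12)
  expect_equal(arrest_probability(1e6, log(10)), 1)
  r <- seq(0, 5, by = 0.25)
  expect_true(all(diff(arrest_probability(r)) > 0))
})

test_that("activation rule: threshold cases via constructed worlds", {
  # lone citizen, no cops: arrest risk is zero, so Active iff grievance > P
  p <- rebellion_params(n_citizens = 1, n_cops = 0, grid_side = 6, vision = 1)
  w <- init_rebellion(p, seed = 1)
  w$perceived_hardship[1] <- 0.9
  w$risk_aversion[1] <- 1
  # grievance = 0.9 * (1 - L)
  expect_equal(citizen_decisions(w, legitimacy = 0.4, propaganda = 0.5), 1L)
  expect_equal(citizen_decisions(w, legitimacy = 0.4, propaganda = 0.54), 0L)
  expect_equal(citizen_decisions(w, legitimacy = 1, propaganda = 0), 0L)

  # citizen sharing the vision box with one cop: floored ratio 1, p = 0.9
  p2 <- rebellion_params(n_citizens = 1, n_cops = 1, grid_side = 8, vision = 7)
  w2 <- init_rebellion(p2, seed = 3)
  view <- edmpc:::abm_local_view_cpp(w2, 1L)
  expect_equal(view$cops_in_vision, 1L)
  expect_equal(view$cop_ratio, 1L)
  w2$perceived_hardship[1] <- 1
  w2$risk_aversion[1] <- 0.2   # g - R * p = (1 - L) - 0.18
  expect_equal(citizen_decisions(w2, legitimacy = 0.5, propaganda = 0.3), 1L)
  expect_equal(citizen_decisions(w2, legitimacy = 0.7, propaganda = 0.3), 0L)
  # propaganda = 1 can never be strictly exceeded
  w2$risk_aversion[1] <- 0
  expect_equal(citizen_decisions(w2, legitimacy = 0.01, propaganda = 1), 0L)
})

test_that("movement: vision zero, full grid, and a single forced destination", {
  p <- rebellion_params(n_citizens = 2, n_cops = 0, grid_side = 4, vision = 0)
  w <- init_rebellion(p, seed = 5)
  expect_equal(move_agent(w, 1)$pos, w$citizen_pos[1])

  # full grid: nobody can move
  pfull <- rebellion_params(n_citizens = 16, n_cops = 0, grid_side = 4, vision = 2)
  wf <- init_rebellion(pfull, seed = 5)
  for (i in c(1, 7, 16)) expect_equal(move_agent(wf, i)$pos, wf$citizen_pos[i])

  # exactly one empty cell within vision: the move is forced
  p1 <- rebellion_params(n_citizens = 15, n_cops = 0, grid_side = 4, vision = 2)
  w1 <- init_rebellion(p1, seed = 5)
  hole <- which(w1$occupancy == 0)
  res <- move_agent(w1, 1)
  expect_equal(res$pos, hole)
  expect_equal(res$world$occupancy[hole], 1L)
})

test_that("enforcement: empty case, forced arrest, capacity bound, jail term range", {
  p <- rebellion_params(n_citizens = 4, n_cops = 1, grid_side = 10, vision = 9,
                        max_jail_term = 5)
  w <- init_rebellion(p, seed = 6)
  expect_equal(cop_enforce(w, 1)$arrested, 0L)  # nobody Active

  w$state[2] <- 1L
  res <- cop_enforce(w, 1)
  expect_equal(res$arrested, 2L)
  expect_equal(res$world$state[2], 2L)
  expect_gte(res$world$jail_remaining[2], 1L)
  expect_lte(res$world$jail_remaining[2], 5L)
  expect_equal(res$world$citizen_pos[2], 0L)
  expect_equal(sum(res$world$occupancy == 2L), 0L)

  pcap <- rebellion_params(n_citizens = 4, n_cops = 1, grid_side = 10,
                           vision = 9, jail_capacity = 0)
  wc <- init_rebellion(pcap, seed = 6)
  wc$state[2] <- 1L
  expect_equal(cop_enforce(wc, 1)$arrested, 0L)
})

test_that("one tick matches the pure-R reference implementation draw for draw", {
  for (seed in c(1, 4, 9)) {
    w <- small_world(seed = seed)
    set.seed(seed + 100)
    for (i in 1:4) w <- step_rebellion(w, 0.6, 0.05)  # stir up some Active/Jailed
    wc <- w; wr <- w
    for (i in 1:3) {
      set.seed(seed + 200 + i)
      wc <- step_rebellion(wc, 0.62, 0.1)
      set.seed(seed + 200 + i)
      wr <- ref_step(wr, 0.62, 0.1)
      expect_identical(wc$state, wr$state)
      expect_identical(wc$citizen_pos, wr$citizen_pos)
      expect_identical(wc$cop_pos, wr$cop_pos)
      expect_identical(wc$occupancy, wr$occupancy)
      expect_identical(wc$jail_remaining, wr$jail_remaining)
    }
  }
})

test_that("tick invariants: conservation, occupancy, jail bookkeeping, release", {
  w <- small_world(seed = 7)
  set.seed(99)
  for (i in 1:60) {
    w <- step_rebellion(w, if (i < 30) 0.6 else 0.82, 0.1)
    cnt <- world_counts(w)
    expect_equal(sum(cnt), 60)
    on_grid <- c(w$citizen_pos[w$citizen_pos > 0], w$cop_pos)
    expect_equal(anyDuplicated(on_grid), 0L)
    expect_true(all((w$state == 2L) == (w$jail_remaining > 0L)))
    expect_true(all((w$state == 2L) == (w$citizen_pos == 0L)))
  }

  # a citizen with one step left is Quiet (back on the grid) next step
  w$state[1] <- 2L; w$jail_remaining[1] <- 1L
  if (w$citizen_pos[1] > 0) {
    w$occupancy[w$citizen_pos[1]] <- 0L
    w$citizen_pos[1] <- 0L
  }
  w2 <- step_rebellion(w, 0.99, 1)
  expect_true(w2$state[1] %in% c(0L, 1L))
  expect_gt(w2$citizen_pos[1], 0L)
})

test_that("decision sets shrink monotonically in propaganda and legitimacy", {
  w <- small_world(seed = 11)
  set.seed(12)
  for (i in 1:10) w <- step_rebellion(w, 0.65, 0.05)
  base <- citizen_decisions(w, 0.65, 0.1)
  for (P in c(0.2, 0.4, 0.8)) {
    higher <- citizen_decisions(w, 0.65, P)
    expect_true(all(higher[base == 0L] == 0L, na.rm = TRUE))
  }
  for (L in c(0.75, 0.9, 1)) {
    higher <- citizen_decisions(w, L, 0.1)
    expect_true(all(higher[base == 0L] == 0L, na.rm = TRUE))
  }
})

test_that("trajectories are pure functions of seed, params and schedule", {
  cfg <- scenario_config(seed = 31, scenario = "uncontrolled", run_length = 40,
                         params = small_params())
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("legitimacy schedule: range, count, determinism, short-run error", {
  s <- sample_legitimacy_schedule(3000, seed = 5)
  expect_equal(nrow(s), 20L)
  expect_true(all(s$value > 0.6 & s$value <= 0.85))
  expect_true(all(diff(s$step) > 0))
  expect_identical(s, sample_legitimacy_schedule(3000, seed = 5))
  expect_error(sample_legitimacy_schedule(15, seed = 1),
               class = "edmpc_config_error")
  s2 <- sample_legitimacy_schedule(400, seed = 2, range = c(0.6, 0.68),
                                   first_step = 301)
  expect_true(all(s2$step >= 301 & s2$step <= 400))
  expect_true(all(s2$value > 0.6 & s2$value <= 0.68))
})

test_that("unknown scenario labels are rejected", {
  expect_error(scenario_config(scenario = "chaos"), class = "edmpc_config_error")
})
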