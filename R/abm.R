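# Agent-based simulator of civil disobedience: an Epstein rebellion variant
# with time-varying government legitimacy and a controllable propaganda
# threshold. Citizens on a toroidal lattice decide each step whether to rebel
# (become Active) by weighing grievance against arrest risk; cops jail Active
# citizens within their vision radius.

#' Simulator parameters
#'
#' Defaults follow the canonical rebellion configuration: 1200 citizens and a
#' 40x40 (1600-cell) torus, 4% cop density, vision radius 7 (Chebyshev), a
#' maximum jail term of 30 steps, and the arrest constant `k = ln(10)` so that
#' a lone cop facing a lone Active citizen arrests with probability 0.90.
#'
#' @param n_citizens Number of citizens.
#' @param n_cops Number of cops.
#' @param grid_side Side length of the square toroidal lattice.
#' @param vision Chebyshev vision radius, in cells, for movement, the local
#'   cop-to-active ratio, and arrests.
#' @param arrest_k Arrest-probability constant `k` in `1 - exp(-k * ratio)`.
#' @param max_jail_term Jail terms are drawn uniformly from `1:max_jail_term`.
#' @param jail_capacity Maximum number of concurrently Jailed citizens.
#' @return A named list of validated parameters.
#' @export
#' @examples
#' rebellion_params(n_citizens = 100, n_cops = 6, grid_side = 12)
rebellion_params <- function(n_citizens = 1200L, n_cops = 64L, grid_side = 40L,
                             vision = 7L, arrest_k = log(10),
                             max_jail_term = 30L, jail_capacity = 500L) {
  p <- list(n_citizens = as.integer(n_citizens), n_cops = as.integer(n_cops),
            grid_side = as.integer(grid_side), vision = as.integer(vision),
            arrest_k = as.numeric(arrest_k),
            max_jail_term = as.integer(max_jail_term),
            jail_capacity = as.integer(jail_capacity))
  if (any(vapply(p, function(x) length(x) != 1 || is.na(x), logical(1)))) {
    abort_config("all simulator parameters must be scalar and non-missing")
  }
  if (p$n_citizens < 1 || p$n_cops < 0 || p$grid_side < 1 || p$vision < 0 ||
      p$arrest_k <= 0 || p$max_jail_term < 1 || p$jail_capacity < 0) {
    abort_config("simulator parameters out of range")
  }
  if (p$n_citizens + p$n_cops > p$grid_side^2) {
    abort_config(sprintf(
      "%d citizens + %d cops exceed the %d cells of the grid",
      p$n_citizens, p$n_cops, p$grid_side^2))
  }
  p
}

#' Initialize a simulation world
#'
#' Places all citizens and cops uniformly at random on distinct cells; every
#' citizen starts Quiet with fixed lifetime draws of risk aversion and
#' perceived hardship from U\[0, 1\].
#'
#' @param params Parameter list from [rebellion_params()].
#' @param seed Optional integer seed; when supplied, `set.seed()` is called so
#'   identical seeds give identical worlds.
#' @return A `rebellion_world` object.
#' @export
#' @examples
#' w <- init_rebellion(rebellion_params(100, 6, 12), seed = 1)
#' world_counts(w)
init_rebellion <- function(params = rebellion_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_citizens
  ncell <- params$grid_side^2
  risk_aversion <- stats::runif(n)
  perceived_hardship <- stats::runif(n)
  pos <- sample.int(ncell, n + params$n_cops)
  occ <- integer(ncell)
  occ[pos] <- seq_len(n + params$n_cops)
  world <- list(
    risk_aversion = risk_aversion,
    perceived_hardship = perceived_hardship,
    state = integer(n),
    jail_remaining = integer(n),
    citizen_pos = pos[seq_len(n)],
    cop_pos = pos[n + seq_len(params$n_cops)],
    occupancy = occ,
    t = 0L,
    params = params)
  class(world) <- "rebellion_world"
  world
}

#' @export
print.rebellion_world <- function(x, ...) {
  cnt <- world_counts(x)
  cat(sprintf(
    "<rebellion_world> t = %d | %d x %d torus | %d citizens (%d Quiet, %d Active, %d Jailed), %d cops\n",
    x$t, x$params$grid_side, x$params$grid_side, x$params$n_citizens,
    cnt[["Quiet"]], cnt[["Active"]], cnt[["Jailed"]], x$params$n_cops))
  invisible(x)
}

#' Citizen state counts
#'
#' @param world A `rebellion_world`.
#' @return Named integer vector with elements `Quiet`, `Active`, `Jailed`.
#' @export
world_counts <- function(world) {
  c(Quiet = sum(world$state == 0L),
    Active = sum(world$state == 1L),
    Jailed = sum(world$state == 2L))
}

#' Advance the simulation one step
#'
#' One synchronous tick: all non-jailed agents act in a uniformly shuffled
#' order (citizens move then reassess Quiet/Active; cops move then arrest one
#' visible Active citizen, subject to jail capacity), then jail terms are
#' decremented and expired citizens are released Quiet onto a random empty
#' cell.
#'
#' @param world A `rebellion_world`.
#' @param legitimacy Current government legitimacy, in (0, 1\].
#' @param propaganda Current propaganda (grievance threshold), in \[0, 1\].
#' @return The updated `rebellion_world` (input is not modified).
#' @export
step_rebellion <- function(world, legitimacy, propaganda) {
  stopifnot(inherits(world, "rebellion_world"))
  if (!is.numeric(legitimacy) || legitimacy <= 0 || legitimacy > 1) {
    abort_config("legitimacy must lie in (0, 1]")
  }
  if (!is.numeric(propaganda) || propaganda < 0 || propaganda > 1) {
    abort_config("propaganda must lie in [0, 1]")
  }
  abm_step_cpp(world, legitimacy, propaganda)
}

#' Grievance of a citizen
#'
#' `grievance = perceived_hardship * (1 - legitimacy)`; vectorized.
#'
#' @param hardship Perceived hardship in \[0, 1\].
#' @param legitimacy Government legitimacy in \[0, 1\].
#' @return Grievance in \[0, 1\].
#' @export
#' @examples
#' grievance(0.5, 0.7)
grievance <- function(hardship, legitimacy) {
  stopifnot(all(hardship >= 0 & hardship <= 1),
            all(legitimacy >= 0 & legitimacy <= 1))
  hardship * (1 - legitimacy)
}

#' Arrest probability from the local cop-to-active ratio
#'
#' `1 - exp(-k * cop_ratio)`; vectorized, monotone increasing in the ratio.
#' With `k = ln(10)` a ratio of 1 yields exactly 0.90.
#'
#' @param cop_ratio Non-negative cop-to-active ratio.
#' @param k Positive arrest constant.
#' @return Probability in \[0, 1).
#' @export
#' @examples
#' arrest_probability(1, log(10))
arrest_probability <- function(cop_ratio, k = log(10)) {
  stopifnot(all(cop_ratio >= 0), k > 0)
  1 - exp(-k * cop_ratio)
}

#' Would-be activation decisions for all citizens
#'
#' Evaluates the threshold rule for every non-jailed citizen at current
#' positions without moving anyone and without consuming random numbers;
#' useful for inspecting monotone effects of legitimacy and propaganda.
#'
#' @param world A `rebellion_world`.
#' @inheritParams step_rebellion
#' @return Integer vector (one per citizen): 1 would be Active, 0 Quiet,
#'   `NA` for Jailed citizens.
#' @export
citizen_decisions <- function(world, legitimacy, propaganda) {
  stopifnot(inherits(world, "rebellion_world"))
  abm_decisions_cpp(world, legitimacy, propaganda)
}

#' Move a single agent (lower-level piece of the tick)
#'
#' Relocates one agent to a uniformly chosen empty cell within its vision
#' radius; the agent stays put when no empty cell is visible.
#'
#' @param world A `rebellion_world`.
#' @param id Agent index: citizen `1..n_citizens`, or cop index with
#'   `type = "cop"`.
#' @param type `"citizen"` or `"cop"`.
#' @return List with the updated `world` and the agent's new `pos` (cell id).
#' @export
move_agent <- function(world, id, type = c("citizen", "cop")) {
  stopifnot(inherits(world, "rebellion_world"))
  type <- match.arg(type)
  gid <- if (type == "cop") world$params$n_citizens + id else id
  res <- abm_move_one_cpp(world, as.integer(gid))
  res
}

#' Cop enforcement sweep (lower-level piece of the tick)
#'
#' One cop jails one uniformly chosen Active citizen within its vision radius,
#' if any is visible and jail capacity allows.
#'
#' @param world A `rebellion_world`.
#' @param cop Cop index in `1..n_cops`.
#' @return List with the updated `world` and `arrested` (citizen id, 0 if no
#'   arrest).
#' @export
cop_enforce <- function(world, cop) {
  stopifnot(inherits(world, "rebellion_world"))
  abm_enforce_one_cpp(world, as.integer(cop))
}

#' Sample a piecewise-constant legitimacy schedule
#'
#' Legitimacy changes at `n_changes` step indices drawn uniformly without
#' replacement from `first_step:run_length`, taking i.i.d. values uniform on
#' the half-open interval `(range[1], range[2]]`.
#'
#' @param run_length Total number of simulation steps.
#' @param seed Optional integer seed.
#' @param n_changes Number of change points (default 20).
#' @param range Half-open value interval; default `(0.6, 0.85]`.
#' @param first_step Earliest step at which a change may occur.
#' @return A `legitimacy_schedule`: tibble with columns `step`, `value`.
#' @export
#' @examples
#' sample_legitimacy_schedule(3000, seed = 1)
sample_legitimacy_schedule <- function(run_length, seed = NULL, n_changes = 20L,
                                       range = c(0.6, 0.85), first_step = 1L) {
  run_length <- as.integer(run_length)
  first_step <- as.integer(first_step)
  n_avail <- run_length - first_step + 1L
  if (n_avail < n_changes) {
    abort_config(sprintf(
      "run of %d steps (from step %d) cannot host %d change points",
      run_length, first_step, n_changes))
  }
  if (!is.null(seed)) set.seed(seed)
  steps <- sort(first_step - 1L + sample.int(n_avail, n_changes))
  # runif() draws in [0, 1); flipping the interval makes the upper end closed.
  values <- range[2] - stats::runif(n_changes) * (range[2] - range[1])
  out <- tibble::tibble(step = steps, value = values)
  class(out) <- c("legitimacy_schedule", class(out))
  attr(out, "run_length") <- run_length
  attr(out, "range") <- range
  out
}

# Expand a schedule into a per-step legitimacy vector, holding `base` before
# the first change point.
schedule_series <- function(schedule, run_length, base) {
  L <- rep(base, run_length)
  if (is.null(schedule)) return(L)
  stopifnot(is.data.frame(schedule), all(c("step", "value") %in% names(schedule)))
  steps <- schedule$step
  if (is.unsorted(steps, strictly = TRUE)) {
    abort_config("schedule change points must be strictly increasing")
  }
  for (i in seq_along(steps)) {
    from <- steps[i]
    if (from > run_length) break
    L[from:run_length] <- schedule$value[i]
  }
  L
}
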