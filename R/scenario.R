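# Scenario runner: nominal (constant legitimacy and propaganda),
# uncontrolled (scheduled legitimacy, constant propaganda) and controlled
# (scheduled legitimacy, propaganda set by the prediction-control loop).
# One root seed drives labeled substreams for the schedule and the world, so
# controlled and uncontrolled twins with the same seed share everything up
# to the moment control engages.

#' Assemble a scenario configuration
#'
#' @param seed Integer root seed for the run.
#' @param scenario `"nominal"`, `"uncontrolled"` or `"controlled"`.
#' @param run_length Number of simulation steps.
#' @param params Simulator parameters from [rebellion_params()].
#' @param legitimacy Constant (nominal) legitimacy, also the pre-schedule
#'   baseline; default 0.82.
#' @param propaganda Constant (nominal) propaganda; default 0.1.
#' @param schedule Legitimacy schedule: `"random"` (values on (0.6, 0.85]
#'   anywhere in the run), `"adversarial"` (values on the low end
#'   (0.6, 0.68], change points only after the controller warm-up), a
#'   data frame of `step`/`value` change points, or `NULL` (constant
#'   legitimacy; forced for the nominal scenario).
#' @param n_changes Number of schedule change points (default 20).
#' @param controller Parameters from [controller_params()] (controlled runs).
#' @param loop Loop configuration from [control_config()] (controlled runs).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            scenario = c("nominal", "uncontrolled", "controlled"),
                            run_length = 3000L, params = rebellion_params(),
                            legitimacy = 0.82, propaganda = 0.1,
                            schedule = NULL, n_changes = 20L,
                            controller = controller_params(),
                            loop = control_config()) {
  if (is.character(scenario) && length(scenario) == 1 &&
      !scenario %in% c("nominal", "uncontrolled", "controlled")) {
    abort_config(sprintf("unknown scenario '%s'", scenario))
  }
  scenario <- match.arg(scenario)
  if (legitimacy <= 0 || legitimacy > 1) abort_config("legitimacy must lie in (0, 1]")
  if (propaganda < 0 || propaganda > 1) abort_config("propaganda must lie in [0, 1]")
  if (is.null(schedule) && scenario != "nominal") schedule <- "random"
  if (scenario == "nominal") schedule <- NULL
  cfg <- list(seed = as.integer(seed), scenario = scenario,
              run_length = as.integer(run_length), params = params,
              legitimacy = legitimacy, propaganda = propaganda,
              schedule = schedule, n_changes = as.integer(n_changes),
              controller = controller, loop = loop)
  class(cfg) <- "scenario_config"
  cfg
}

resolve_schedule <- function(config) {
  sch <- config$schedule
  if (is.null(sch)) return(NULL)
  if (is.data.frame(sch)) return(sch)
  seed <- derive_seed(config$seed, "schedule")
  switch(
    as.character(sch),
    random = sample_legitimacy_schedule(
      config$run_length, seed = seed, n_changes = config$n_changes,
      range = c(0.6, 0.85)),
    adversarial = sample_legitimacy_schedule(
      config$run_length, seed = seed, n_changes = config$n_changes,
      range = c(0.6, 0.68),
      first_step = min(config$loop$warmup_obs + 1L, config$run_length)),
    abort_config(sprintf("unknown schedule style '%s'", sch)))
}

#' Run a full simulation scenario
#'
#' Runs the agent-based model for `run_length` steps under one of three
#' scenarios and returns the observation table. The returned tibble carries
#' the resolved schedule, the scenario label and (for controlled runs) the
#' s-map localization and engagement step as attributes.
#'
#' @param config A [scenario_config()].
#' @return Observation tibble with columns
#'   `time, Quiet, Active, Jailed, Legitimacy, Propaganda`.
#' @export
#' @examples
#' \donttest{
#' tab <- run_scenario(scenario_config(seed = 1, scenario = "nominal",
#'                                     run_length = 200))
#' }
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  schedule <- resolve_schedule(config)
  L_series <- schedule_series(schedule, config$run_length, config$legitimacy)
  set.seed(derive_seed(config$seed, "world"))
  world <- init_rebellion(config$params, seed = NULL)
  meta <- list(theta = NA_real_, engaged_at = NA_integer_)
  if (config$scenario == "controlled") {
    res <- control_loop(world, L_series, nominal_propaganda = config$propaganda,
                        controller = config$controller, config = config$loop)
    table <- res$table
    meta$theta <- res$theta
    meta$engaged_at <- res$engaged_at
  } else {
    n <- config$run_length
    Q <- A <- J <- integer(n)
    for (t in seq_len(n)) {
      world <- step_rebellion(world, L_series[t], config$propaganda)
      cnt <- world_counts(world)
      Q[t] <- cnt[["Quiet"]]; A[t] <- cnt[["Active"]]; J[t] <- cnt[["Jailed"]]
    }
    table <- tibble::tibble(time = seq_len(n), Quiet = as.numeric(Q),
                            Active = as.numeric(A), Jailed = as.numeric(J),
                            Legitimacy = L_series,
                            Propaganda = rep(config$propaganda, n))
  }
  attr(table, "scenario") <- config$scenario
  attr(table, "seed") <- config$seed
  attr(table, "n_citizens") <- config$params$n_citizens
  attr(table, "schedule") <- schedule
  attr(table, "theta") <- meta$theta
  attr(table, "engaged_at") <- meta$engaged_at
  table
}
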