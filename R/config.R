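# Structured-text (YAML) run configurations with a strict schema: unknown
# keys are rejected before any computation, and a written configuration
# reads back to an identical object.

config_schema <- list(
  top = c("seed", "scenario", "run_length", "legitimacy", "propaganda",
          "schedule", "n_changes", "params", "controller", "loop"),
  params = c("n_citizens", "n_cops", "grid_side", "vision", "arrest_k",
             "max_jail_term", "jail_capacity"),
  controller = c("P_min", "P_max", "m", "A_0"),
  loop = c("warmup_obs", "theta", "theta_grid", "select_frac",
           "max_select_queries", "method", "embedding"),
  embedding = c("columns", "lags", "target", "Tp", "cross"),
  schedule = c("step", "value"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort_config(sprintf("unknown key%s in %s: %s",
                         if (length(unknown) > 1) "s" else "", where,
                         paste(unknown, collapse = ", ")))
  }
}

#' Read a scenario configuration from YAML
#'
#' Validates every section against the configuration schema (unknown keys
#' are rejected) and returns a [scenario_config()]. Omitted keys take the
#' constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return A `scenario_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort_config("config file must contain a YAML mapping")
  check_keys(raw, config_schema$top, "config")
  grab <- function(x, name, default) if (name %in% names(x)) x[[name]] else default
  params <- raw$params %||% list()
  check_keys(params, config_schema$params, "params")
  params <- do.call(rebellion_params, params)
  controller <- raw$controller %||% list()
  check_keys(controller, config_schema$controller, "controller")
  controller <- do.call(controller_params, controller)
  loop_raw <- raw$loop %||% list()
  check_keys(loop_raw, config_schema$loop, "loop")
  emb <- loop_raw$embedding
  loop_args <- loop_raw[setdiff(names(loop_raw), "embedding")]
  if (!is.null(emb)) {
    check_keys(emb, config_schema$embedding, "loop$embedding")
    loop_args$spec <- embedding_spec(
      columns = unlist(emb$columns), lags = unlist(emb$lags),
      target = emb$target, Tp = grab(emb, "Tp", 1L),
      cross = grab(emb, "cross", TRUE))
  }
  if ("theta_grid" %in% names(loop_args)) {
    loop_args$theta_grid <- unlist(loop_args$theta_grid)
  }
  loop <- do.call(control_config, loop_args)
  schedule <- raw$schedule
  if (is.list(schedule) && !is.null(names(schedule))) {
    check_keys(schedule, config_schema$schedule, "schedule")
    schedule <- tibble::tibble(step = as.integer(unlist(schedule$step)),
                               value = as.numeric(unlist(schedule$value)))
  }
  scenario_config(
    seed = grab(raw, "seed", 1L),
    scenario = grab(raw, "scenario", "nominal"),
    run_length = grab(raw, "run_length", 3000L),
    params = params,
    legitimacy = grab(raw, "legitimacy", 0.82),
    propaganda = grab(raw, "propaganda", 0.1),
    schedule = schedule,
    n_changes = grab(raw, "n_changes", 20L),
    controller = controller, loop = loop)
}

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `config`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- config$loop$spec
  out <- list(
    seed = config$seed, scenario = config$scenario,
    run_length = config$run_length, legitimacy = config$legitimacy,
    propaganda = config$propaganda,
    n_changes = config$n_changes,
    params = config$params,
    controller = config$controller,
    loop = c(config$loop[setdiff(names(config$loop), c("spec", "theta"))],
             list(embedding = list(
               columns = spec$coords$column, lags = spec$coords$lag,
               target = spec$target, Tp = spec$Tp, cross = FALSE))))
  if (!is.null(config$loop$theta)) out$loop$theta <- config$loop$theta
  if (!is.null(config$schedule)) {
    out$schedule <- if (is.data.frame(config$schedule)) {
      list(step = config$schedule$step, value = config$schedule$value)
    } else config$schedule
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(config)
}
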