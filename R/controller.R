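# The propaganda controller: a logistic law mapping the predicted number of
# Active citizens to a propaganda level, and the closed prediction-control
# loop that couples the s-map process model to the simulator.

#' Logistic controller parameters
#'
#' `P(t) = (P_max - P_min) / (1 + exp(-m * (A(t) - A_0))) + P_min`, where
#' `A(t)` is the state-space predicted number of Active citizens. Defaults
#' are the operating values `P_min = 0.06`, `P_max = 0.6`, `m = 0.05`,
#' `A_0 = 50`.
#'
#' @param P_min,P_max Lower and upper propaganda bounds (`P_min < P_max`).
#' @param m Logistic slope (`> 0`).
#' @param A_0 Active-count midpoint of the logistic.
#' @return A validated parameter list.
#' @export
controller_params <- function(P_min = 0.06, P_max = 0.6, m = 0.05, A_0 = 50) {
  if (!(P_min < P_max)) abort_config("controller requires P_min < P_max")
  if (m <= 0) abort_config("controller slope m must be positive")
  list(P_min = P_min, P_max = P_max, m = m, A_0 = A_0)
}

#' Propaganda response to a predicted Active count
#'
#' Evaluates the logistic control law; strictly increasing in the prediction,
#' bounded in `(P_min, P_max)`. The prediction is used as-is (not rounded).
#'
#' @param A_pred Predicted number of Active citizens (finite, may be
#'   non-integer); vectorized.
#' @param params Parameters from [controller_params()].
#' @return Propaganda level(s) in `(P_min, P_max)`.
#' @export
#' @examples
#' propaganda_response(50)  # midpoint: 0.06 + 0.54 / 2
propaganda_response <- function(A_pred, params = controller_params()) {
  stopifnot(all(is.finite(A_pred)))
  (params$P_max - params$P_min) /
    (1 + exp(-params$m * (A_pred - params$A_0))) + params$P_min
}

#' Control-loop configuration
#'
#' @param warmup_obs Number of recorded observations before the first
#'   controller estimate; until then propaganda is held at the nominal
#'   constant. Must be at least the maximum embedding lag plus `Tp`.
#' @param spec Embedding used by the process model; its `Tp` is the forecast
#'   horizon.
#' @param theta Fixed s-map localization, or `NULL` to select it once at
#'   warm-up end via [select_theta()] on the warm-up library.
#' @param theta_grid Candidate grid used when `theta` is `NULL`.
#' @param select_frac Fraction of the warm-up observations used as the
#'   library during theta selection (the remainder are scored).
#' @param max_select_queries Cap on scored queries during theta selection.
#' @param method Process model used in the loop: `"smap"` (default) or
#'   `"simplex"`.
#' @return A validated configuration list.
#' @export
control_config <- function(warmup_obs = 3000L, spec = generalized_embedding(Tp = 5L),
                           theta = NULL, theta_grid = default_theta_grid(),
                           select_frac = 0.7, max_select_queries = 200L,
                           method = c("smap", "simplex")) {
  method <- match.arg(method)
  warmup_obs <- as.integer(warmup_obs)
  maxlag <- max(spec$coords$lag)
  if (warmup_obs < maxlag + spec$Tp) {
    abort_config(sprintf(
      "warmup_obs = %d is below max lag + Tp = %d: no state vector would exist",
      warmup_obs, maxlag + spec$Tp))
  }
  if (!is.null(theta) && theta < 0) abort_config("theta must be non-negative")
  list(warmup_obs = warmup_obs, spec = spec, theta = theta,
       theta_grid = theta_grid, select_frac = select_frac,
       max_select_queries = as.integer(max_select_queries), method = method)
}

#' Run the closed prediction-control loop
#'
#' Each step the latest observation joins the growing state-space library;
#' before `warmup_obs` observations have been recorded propaganda is held at
#' `nominal_propaganda`. Afterwards the current query state (latest
#' Quiet/Jailed lags) is formed, the Active count `Tp` steps ahead is
#' predicted from the library (s-map by default), and the logistic controller
#' sets the propaganda applied to the very next simulator step. No future
#' data is ever used; on prediction failure the previous propaganda is held
#' and a warning is logged.
#'
#' @param world A `rebellion_world` from [init_rebellion()].
#' @param legitimacy_series Per-step legitimacy values (length = run length).
#' @param nominal_propaganda Propaganda held during warm-up.
#' @param controller Parameters from [controller_params()].
#' @param config Loop configuration from [control_config()].
#' @return List with `table` (the observation tibble, where `Propaganda`
#'   records the value applied at each step), `theta` (the localization used
#'   once engaged, `NA` if never engaged), and `engaged_at` (the step of the
#'   first controller estimate, `NA` if never).
#' @export
control_loop <- function(world, legitimacy_series, nominal_propaganda = 0.1,
                         controller = controller_params(),
                         config = control_config()) {
  n <- length(legitimacy_series)
  spec <- config$spec
  Tp <- spec$Tp
  maxlag <- max(spec$coords$lag)
  cols <- unique(c(spec$coords$column, spec$target))
  known <- c("Quiet", "Active", "Jailed", "Legitimacy", "Propaganda")
  if (!all(cols %in% known)) {
    abort_config("control-loop embedding may only use recorded observation columns")
  }
  obs <- matrix(NA_real_, n, length(known), dimnames = list(NULL, known))
  # growing library: one row per time s, filled once target(s + Tp) is known
  libX <- matrix(NA_real_, n, spec$E)
  libY <- rep(NA_real_, n)
  lib_hi <- 0L   # rows maxlag+1 .. lib_hi are populated
  theta <- config$theta
  engaged_at <- NA_integer_
  P_prev <- nominal_propaganda
  for (t in seq_len(n)) {
    n_obs <- t - 1L
    if (n_obs < config$warmup_obs) {
      P <- nominal_propaganda
    } else {
      if (is.null(theta)) {
        warm <- tibble::as_tibble(as.data.frame(obs[seq_len(n_obs), , drop = FALSE]))
        warm <- dplyr::bind_cols(tibble::tibble(time = seq_len(n_obs)), warm)
        split_at <- max(maxlag + Tp + 1L, floor(config$select_frac * n_obs))
        sel <- tryCatch(
          select_theta(warm, spec, config$theta_grid,
                       lib = c(1L, split_at), pred = c(split_at + 1L, n_obs),
                       max_queries = config$max_select_queries),
          edmpc_insufficient_library = function(e) NULL,
          edmpc_empty_library = function(e) NULL)
        if (is.null(sel)) {
          # not enough observations yet to score candidates: hold propaganda
          # and retry at the next step
          rlang::warn("control loop: theta selection deferred; holding propaganda",
                      .frequency = "once", .frequency_id = "edmpc_ctl_sel")
          world <- step_rebellion(world, legitimacy_series[t], P_prev)
          cnt <- world_counts(world)
          obs[t, ] <- c(cnt[["Quiet"]], cnt[["Active"]], cnt[["Jailed"]],
                        legitimacy_series[t], P_prev)
          next
        }
        theta <- sel$theta
      }
      # extend library with every row whose future is now observed
      new_hi <- n_obs - Tp
      if (new_hi > lib_hi) {
        for (s in (max(lib_hi, maxlag) + 1L):new_hi) {
          libX[s, ] <- vapply(seq_len(spec$E), function(j)
            obs[s - spec$coords$lag[j], spec$coords$column[j]], numeric(1))
          libY[s] <- obs[s + Tp, spec$target]
        }
        lib_hi <- new_hi
      }
      rows_ok <- (maxlag + 1L):lib_hi
      rows_ok <- rows_ok[stats::complete.cases(libX[rows_ok, , drop = FALSE]) &
                           !is.na(libY[rows_ok])]
      y <- vapply(seq_len(spec$E), function(j)
        obs[n_obs - spec$coords$lag[j], spec$coords$column[j]], numeric(1))
      if (length(rows_ok) < spec$E + 2 || anyNA(y)) {
        rlang::warn("control loop: insufficient library for a prediction; holding propaganda",
                    .frequency = "once", .frequency_id = "edmpc_ctl_hold")
        P <- P_prev
      } else {
        A_hat <- predict_one(libX[rows_ok, , drop = FALSE], libY[rows_ok], y,
                             config$method, theta)
        P <- propaganda_response(A_hat, controller)
        if (is.na(engaged_at)) engaged_at <- t
      }
    }
    world <- step_rebellion(world, legitimacy_series[t], P)
    cnt <- world_counts(world)
    obs[t, ] <- c(cnt[["Quiet"]], cnt[["Active"]], cnt[["Jailed"]],
                  legitimacy_series[t], P)
    P_prev <- P
  }
  table <- tibble::tibble(
    time = seq_len(n), Quiet = obs[, "Quiet"], Active = obs[, "Active"],
    Jailed = obs[, "Jailed"], Legitimacy = obs[, "Legitimacy"],
    Propaganda = obs[, "Propaganda"])
  list(table = table, world = world,
       theta = if (is.null(theta)) NA_real_ else theta,
       engaged_at = engaged_at)
}

# One forecast from raw library matrices (used by the online loop).
predict_one <- function(X, y_fut, q, method, theta) {
  d <- sqrt(colSums((t(X) - q)^2))
  if (method == "simplex") {
    k <- min(ncol(X) + 1L, length(d))
    ord <- order(d)[seq_len(k)]
    simplex_combine(d[ord], y_fut[ord])
  } else {
    D <- mean(d)
    w <- if (D > 0) exp(-theta * d / D) else rep(1, length(d))
    co <- smap_solve(X, y_fut, w)
    unname(co[1] + sum(co[-1] * q))
  }
}
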