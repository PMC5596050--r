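# Backward induction of the value function and policy extraction.

#' Behaviours available in a given state
#'
#' Foraging (1, 2) requires daylight and (baseline) normothermia; with the
#' shallow-forage variant it is allowed while depth is below
#' `shallow_forage_limit`. Resting in safe habitat (3) requires normothermia
#' (at night it keeps its own safe-habitat risk class). Cooling (4)
#' requires depth below `Y_max`; rewarming (5) and holding depth (6) require
#' being hypothermic.
#'
#' @param params a `winter_params` object.
#' @param y hypothermia depth, degC (grid node).
#' @param t period index (0-based).
#' @return sorted integer vector of feasible behaviours.
#' @export
feasible_behaviours <- function(params, y, t) {
  d <- params$derived
  yi <- .y_index(params, y)
  pod <- t %% params$periods_per_day
  is_day <- pod >= params$daylight_start & pod < params$daylight_end
  out <- integer(0)
  if (is_day && yi < d$shallow_nodes) out <- c(out, 1L, 2L)
  if (yi == 0L) out <- c(out, 3L)
  if (yi < params$n_hypo_steps) out <- c(out, 4L)
  if (yi > 0L) out <- c(out, 5L, 6L)
  sort(out)
}

#' One-behaviour expected survival (the bracketed term of the recursion)
#'
#' Computes `(1 - beta_i) * sum_k prob_k F_next(x_k, y', w_k)` for one
#' behaviour: the probability-weighted next-period survival over the foraging
#' and weather branches, fat interpolated between grid nodes, times this
#' period's survival factor. This is the quantity the solver maximises over
#' behaviours.
#'
#' @param params a `winter_params` object.
#' @param F_next numeric array of next-period values, dim
#'   `(n_fat_steps+1, n_hypo_steps+1, 2)` (weather G then B).
#' @param behaviour integer 1..6, feasible at `(y, t)`.
#' @param x,y,weather,t current state.
#' @return expected survival probability.
#' @export
expected_value <- function(params, F_next, behaviour, x, y,
                           weather = c("G", "B"), t) {
  weather <- match.arg(weather)
  tr <- fat_transition(params, behaviour, x, y, weather, t)
  y2 <- tr$next_y[1]
  yi <- .y_index(params, y2)
  v <- 0
  for (r in seq_len(nrow(tr))) {
    wi <- if (tr$next_weather[r] == "G") 1L else 2L
    v <- v + tr$prob[r] *
      interpolate_value(F_next[, yi + 1L, wi], tr$next_fat[r], params)
  }
  (1 - predation_hazard(params, behaviour, x, y2, t)) * v
}

# assemble the flat input list the C++ kernel consumes
.cpp_inputs <- function(params) {
  p <- params; d <- p$derived
  grid <- build_grid(p)
  list(
    nf = p$n_fat_steps + 1L, ny = p$n_hypo_steps + 1L,
    T = d$n_periods_total, ppd = p$periods_per_day,
    d_start = p$daylight_start, d_end = p$daylight_end,
    sigma_nodes = as.integer(d$sigma_nodes),
    mode = match(p$daytime_hypo_risk_mode,
                 c("constant_high", "linear_eq14", "safe_as_rest")) - 1L,
    shallow_nodes = as.integer(d$shallow_nodes),
    interp_mode = if (p$interp_method == "steffen") 1L else 0L,
    dx = d$fat_step, Xmax = p$X_max,
    CRMp = d$C_RM_period, gamma = p$gamma, delta = p$delta,
    eps = p$epsilon, CWU_per = d$C_WU_per_period,
    xcr = p$x_cr, alpha = p$alpha_exp,
    pGG = p$p_GG, pBB = p$p_BB,
    fat = grid$fat_values,
    xC = warmup_fat_requirement(p, grid$hypo_values),
    mu = p$mu, lambda = p$lambda,
    Gp = c(d$G_succ_period, 0, 0, 0, 0),
    beta_day = d$beta_day_period,
    end_p = d$end_p,
    bhd = d$beta_hypo_day_period, bhn = d$beta_hypo_night_period,
    brn = d$beta_night_rest_period
  )
}

#' Solve the winter survival model by backward induction
#'
#' Iterates the survival recursion backwards from the horizon (a daybreak,
#' where the terminal reward is 1 iff fat covers the warm-up requirement)
#' through the uncertain end-of-winter window to day 1, storing the optimal
#' behaviour for every (fat, depth, weather, period) cell. Value ties are
#' broken towards the lower-hazard behaviour, then the lower index.
#'
#' @param params a `winter_params` object.
#' @param keep_periods periods (0-based) at which to retain the full value
#'   function; the day-1 daybreak start period is always kept. Use
#'   `keep_periods = "all"` on small models to retain every period.
#' @return A `winter_policy` object: `policy` (raw array, dims fat x depth x
#'   weather x period), `F_keep` (numeric array over kept periods),
#'   `keep_periods`, and `start_survival`, the survival probability at the
#'   forward-simulation start state (day-1 daybreak, `x_start`, normothermic,
#'   good weather).
#' @export
solve_policy <- function(params, keep_periods = NULL) {
  stopifnot(inherits(params, "winter_params"))
  d <- params$derived
  if (identical(keep_periods, "all")) keep_periods <- 0:d$n_periods_total
  keep <- sort(unique(as.integer(c(d$start_period, keep_periods))))
  stopifnot(all(keep >= 0 & keep <= d$n_periods_total))
  P <- .cpp_inputs(params)
  res <- cpp_solve(P, keep)
  nf <- P$nf; ny <- P$ny
  dim(res$policy) <- c(nf, ny, 2L, d$n_periods_total)
  Fk <- res$F_keep
  dim(Fk) <- c(nf, ny, 2L, length(keep))
  fit <- list(params = params, policy = res$policy, F_keep = Fk,
              keep_periods = keep)
  fit$start_survival <- survival_at(fit, params$x_start, y = 0,
                                    weather = "G", period = d$start_period)
  class(fit) <- "winter_policy"
  fit
}

#' Survival probability at an arbitrary state
#'
#' Reads the stored value function at a kept period, interpolating in fat.
#'
#' @param fit a `winter_policy` from [solve_policy()].
#' @param x fat, kJ.
#' @param y depth, degC (grid node).
#' @param weather `"G"` or `"B"`.
#' @param period a period retained in `fit$keep_periods` (default: the
#'   forward-start daybreak).
#' @return survival probability.
#' @export
survival_at <- function(fit, x, y = 0, weather = c("G", "B"), period = NULL) {
  weather <- match.arg(weather)
  p <- fit$params
  if (is.null(period)) period <- p$derived$start_period
  kidx <- match(period, fit$keep_periods)
  if (is.na(kidx)) stop("period ", period, " was not retained; pass it via ",
                        "keep_periods= when solving", call. = FALSE)
  yi <- .y_index(p, y)
  wi <- if (weather == "G") 1L else 2L
  interpolate_value(fit$F_keep[, yi + 1L, wi, kidx], x, p)
}

#' Optimal behaviour at a state
#'
#' @param fit a `winter_policy`.
#' @param x fat, kJ (snapped to the nearest grid node, as in the forward
#'   simulation).
#' @param y depth, degC (grid node).
#' @param weather `"G"` or `"B"`.
#' @param period period index, `0 <= period < T`.
#' @return behaviour index 1..6.
#' @export
optimal_behaviour <- function(fit, x, y = 0, weather = c("G", "B"), period) {
  weather <- match.arg(weather)
  p <- fit$params
  k <- min(max(as.integer(round(x / p$derived$fat_step)), 0L), p$n_fat_steps)
  yi <- .y_index(p, y)
  wi <- if (weather == "G") 1L else 2L
  as.integer(fit$policy[k + 1L, yi + 1L, wi, period + 1L])
}

#' Tabulate the optimal policy for selected days
#'
#' @param fit a `winter_policy`.
#' @param days integer day indices (1-based).
#' @return data.frame with `day`, `period`, `period_of_day`, `fat_kJ`,
#'   `hypo_C`, `weather`, `behaviour`.
#' @export
policy_frame <- function(fit, days) {
  p <- fit$params; d <- p$derived
  grid <- build_grid(p)
  ts <- unlist(lapply(days, function(dd)
    ((dd - 1L) * p$periods_per_day) + 0:(p$periods_per_day - 1L)))
  ts <- ts[ts < d$n_periods_total]
  cells <- expand.grid(fat_kJ = grid$fat_values, hypo_C = grid$hypo_values,
                       weather = c("G", "B"), period = ts,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$behaviour <- as.integer(fit$policy[cbind(
    match(cells$fat_kJ, grid$fat_values),
    match(cells$hypo_C, grid$hypo_values),
    match(cells$weather, c("G", "B")),
    cells$period + 1L)])
  cells$day <- cells$period %/% p$periods_per_day + 1L
  cells$period_of_day <- cells$period %% p$periods_per_day
  cells[c("day", "period", "period_of_day", "fat_kJ", "hypo_C", "weather",
          "behaviour")]
}

#' Tabulate the value function at the kept periods
#'
#' @param fit a `winter_policy`.
#' @return data.frame with `period`, `fat_kJ`, `hypo_C`, `weather`, `F`.
#' @export
value_frame <- function(fit) {
  p <- fit$params
  grid <- build_grid(p)
  cells <- expand.grid(fat_kJ = grid$fat_values, hypo_C = grid$hypo_values,
                       weather = c("G", "B"), period = fit$keep_periods,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$F <- as.numeric(fit$F_keep)
  cells[c("period", "fat_kJ", "hypo_C", "weather", "F")]
}

#' Write policy or value tables as CSV
#'
#' @param fit a `winter_policy`.
#' @param file output path.
#' @param days day indices for the policy table.
#' @return `file`, invisibly.
#' @export
write_policy_csv <- function(fit, file, days) {
  utils::write.csv(policy_frame(fit, days), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_policy_csv
#' @export
write_value_csv <- function(fit, file) {
  utils::write.csv(value_frame(fit), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.winter_policy <- function(x, ...) {
  p <- x$params
  cat("Optimal winter policy\n")
  cat(sprintf("  lattice: %d fat x %d depth x 2 weather x %d periods\n",
              p$n_fat_steps + 1L, p$n_hypo_steps + 1L,
              p$derived$n_periods_total))
  cat(sprintf("  survival at start state (day 1 daybreak, %g kJ, normothermic, good weather): %.4f\n",
              p$x_start, x$start_survival))
  invisible(x)
}
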