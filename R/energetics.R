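# Per-period energy gains/expenditures and the stochastic fat transition.
#
# Behaviours are indexed 1..6:
#   1 high-intensity foraging, 2 cautious foraging, 3 rest in safe habitat,
#   4 decrease body temperature, 5 increase body temperature,
#   6 stay at constant hypothermic temperature.

#' Per-period activity- and mass-dependent cost (normothermic behaviours)
#'
#' `C_i = C_RM (1 + mu_i + mu_i x / X_max)` per period: a lean foraging bird
#' pays 3x resting metabolism (mu = 2), a maximally fat one 5x; resting
#' behaviours pay exactly resting metabolism.
#'
#' @param params a `winter_params` object.
#' @param behaviour integer 1..6.
#' @param x fat reserves, kJ, in `[0, X_max]`.
#' @return cost in kJ per 5-min period.
#' @export
activity_cost <- function(params, behaviour, x) {
  if (!(length(behaviour) == 1L && behaviour %in% 1:6))
    stop("unknown behaviour: ", behaviour, call. = FALSE)
  stopifnot(all(x >= 0 & x <= params$X_max))
  mu <- params$mu[behaviour]
  params$derived$C_RM_period * (1 + mu + mu * x / params$X_max)
}

#' Per-period expenditure of a hypothermic bird
#'
#' `(C_RM - eps C_RM y/Y_max) gamma_w` plus, while actively rewarming, a
#' pro-rated share of the extra warm-up cost `C_WU` (the surcharge is not
#' weather-scaled). At maximal depth with `eps = 0.3` the bird saves exactly
#' 30% of resting expenditure.
#'
#' @param params a `winter_params` object.
#' @param y hypothermia depth, degC in `[0, Y_max]`.
#' @param weather `"G"` or `"B"`.
#' @param warming logical; `TRUE` while performing the rewarming behaviour.
#' @return cost in kJ per 5-min period.
#' @export
hypothermic_cost <- function(params, y, weather = c("G", "B"), warming = FALSE) {
  weather <- match.arg(weather)
  if (any(y < 0 | y > params$Y_max))
    stop("hypothermia depth outside [0, Y_max]", call. = FALSE)
  gw <- if (weather == "B") params$gamma else 1
  crm <- params$derived$C_RM_period
  (crm - params$epsilon * crm * (y / params$Y_max)) * gw +
    if (warming) params$derived$C_WU_per_period else 0
}

#' Stochastic fat transition for one period
#'
#' Combines foraging success (probability `lambda`; an unsuccessful period
#' still yields a fraction `delta` of the gain) with the weather transition:
#' the expenditure term is multiplied by `gamma` in branches where the coming
#' period's weather is bad. Foraging behaviours therefore have four outcomes;
#' behaviours with `lambda = 1` collapse to the two weather branches. Next-period
#' fat is clamped at `X_max`; values at or below 0 mean starvation.
#'
#' @param params a `winter_params` object.
#' @param behaviour integer 1..6.
#' @param x current fat, kJ.
#' @param y current hypothermia depth, degC (grid node).
#' @param weather current weather, `"G"` or `"B"`.
#' @param t current period index (0-based); decides daylight.
#' @return data.frame with columns `next_fat` (kJ), `prob`, `next_weather`,
#'   `success`, and the post-decision depth `next_y` (constant per call).
#' @export
fat_transition <- function(params, behaviour, x, y, weather = c("G", "B"), t) {
  weather <- match.arg(weather)
  feas <- feasible_behaviours(params, y, t)
  if (!behaviour %in% feas)
    stop(sprintf("behaviour %d infeasible at depth y = %g, period %d",
                 behaviour, y, t), call. = FALSE)
  d <- params$derived
  p_stay <- if (weather == "G") params$p_GG else params$p_BB
  w_next <- c(weather, setdiff(c("G", "B"), weather))
  p_w <- c(p_stay, 1 - p_stay)

  if (behaviour %in% 4:6) {
    y2 <- step_hypothermia(params, y, behaviour)
    warming <- behaviour == 5L
    cost <- vapply(w_next, function(w)
      hypothermic_cost(params, y2, w, warming), numeric(1))
    out <- data.frame(
      next_fat = pmin(x - cost, params$X_max),
      prob = p_w, next_weather = w_next, success = TRUE, next_y = y2,
      stringsAsFactors = FALSE
    )
  } else {
    lam <- params$lambda[behaviour]
    gain_s <- if (behaviour <= 2) d$G_succ_period[behaviour] else 0
    gain_f <- gain_s * params$delta
    cost <- activity_cost(params, behaviour, x) *
      ifelse(w_next == "B", params$gamma, 1)
    if (lam < 1) {
      out <- data.frame(
        next_fat = pmin(x + c(gain_s - cost, gain_f - cost), params$X_max),
        prob = c(lam * p_w, (1 - lam) * p_w),
        next_weather = rep(w_next, 2),
        success = rep(c(TRUE, FALSE), each = 2),
        next_y = y, stringsAsFactors = FALSE
      )
    } else {
      out <- data.frame(
        next_fat = pmin(x + gain_s - cost, params$X_max),
        prob = p_w, next_weather = w_next, success = TRUE, next_y = y,
        stringsAsFactors = FALSE
      )
    }
  }
  rownames(out) <- NULL
  out
}
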