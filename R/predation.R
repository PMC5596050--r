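# Per-period predation hazards.
#
# Daylight hazards for normothermic behaviours are mass-dependent and
# accelerate above the critical fat load x_cr:
#   beta_i(x) = beta_iB (1 + ((x - x_cr)/x_cr)^alpha)  for x > x_cr,
# where beta_iB is the per-period baseline for a lean bird (obtained from the
# daily value by compounding). Hypothermic behaviours carry a constant high
# hazard in daylight (baseline mode) and a low constant hazard at night;
# resting at night shares the night risk class (it is the normothermic limit
# of sleeping in a cavity).

.mass_multiplier <- function(params, x) {
  m <- rep(1, length(x))
  over <- x > params$x_cr
  m[over] <- 1 + ((x[over] - params$x_cr) / params$x_cr)^params$alpha_exp
  m
}

#' Per-period predation hazard
#'
#' @param params a `winter_params` object.
#' @param behaviour integer 1..6.
#' @param x fat reserves, kJ (vectorised).
#' @param y hypothermia depth, degC; for behaviours 4-6 pass the
#'   post-decision depth (a bird entering hypothermia in daylight is exposed to
#'   the hypothermic risk class the same period).
#' @param t period index (0-based); decides day vs night.
#' @return hazard probability per 5-min period, in `[0, 1)`.
#' @export
predation_hazard <- function(params, behaviour, x, y = 0, t) {
  if (!(length(behaviour) == 1L && behaviour %in% 1:6))
    stop("unknown behaviour: ", behaviour, call. = FALSE)
  d <- params$derived
  pod <- t %% params$periods_per_day
  is_day <- pod >= params$daylight_start & pod < params$daylight_end
  if (behaviour <= 2L) {
    if (!is_day)
      stop("foraging behaviours are masked at night", call. = FALSE)
    return(pmin(d$beta_day_period[behaviour] * .mass_multiplier(params, x),
                1 - 1e-12))
  }
  if (behaviour == 3L) {
    if (is_day)
      return(pmin(d$beta_day_period[3] * .mass_multiplier(params, x), 1 - 1e-12))
    # resting at night keeps behaviour 3's own (safe-habitat) risk; a
    # normothermic sleeper can still react to a cavity predator, so its hazard
    # is lower than the hypothermic night class
    return(rep(d$beta_night_rest_period, length(x)))
  }
  # behaviours 4-6
  if (!is_day) return(rep(d$beta_hypo_night_period, length(x)))
  mode <- params$daytime_hypo_risk_mode
  beta3 <- d$beta_day_period[3] * .mass_multiplier(params, x)
  h <- switch(mode,
    constant_high = rep(d$beta_hypo_day_period, length(x)),
    linear_eq14   = beta3 + (y / params$Y_max) * d$beta_hypo_day_period,
    safe_as_rest  = beta3
  )
  pmin(h, 1 - 1e-12)
}
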