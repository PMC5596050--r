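# Uncertain end of winter and the terminal reward.
#
# Winter can end at any daybreak from day T_f_day onwards, with a hazard that
# makes the end daybreak uniform over the candidates: at the k-th of K
# candidate daybreaks the conditional probability of ending is 1/(K - k + 1),
# reaching 1 at the horizon T. A bird alive when winter ends scores 1 if its
# fat covers the warm-up requirement x_C(y), else 0; at all other periods the
# reward is 0.

#' Probability that winter ends at period t
#'
#' Non-zero only at candidate daybreaks within the end window; equals 1 at the
#' final period `T`.
#'
#' @param params a `winter_params` object.
#' @param t period index (0-based), vectorised.
#' @return per-period ending probability.
#' @export
end_probability <- function(params, t) {
  d <- params$derived
  out <- numeric(length(t))
  ok <- t >= 0 & t <= d$n_periods_total
  out[ok] <- d$end_p[t[ok] + 1L]
  out
}

#' Terminal reward at a candidate end period
#'
#' @param params a `winter_params` object.
#' @param x fat reserves, kJ.
#' @param y hypothermia depth, degC (grid node).
#' @param t period index.
#' @return 1 if the period is a daybreak in the end window and `x >= x_C(y)`,
#'   else 0.
#' @export
terminal_reward <- function(params, x, y, t) {
  d <- params$derived
  pod <- t %% params$periods_per_day
  in_window <- t >= d$T_f_period & t <= d$n_periods_total &
    pod == params$daylight_start
  as.numeric(in_window & x >= warmup_fat_requirement(params, y))
}
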