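# Hypothermia state dynamics and the warm-up fat requirement.
#
# Body temperature moves in fixed per-period steps sigma = eta = Y_max /
# n_warmup_periods, so a full rewarm from maximal depth takes n_warmup_periods
# periods (30 min at defaults). Transitions always land on hypothermia grid
# nodes because n_hypo_steps is a multiple of n_warmup_periods.

.y_index <- function(params, y) {
  step <- params$derived$hypo_step
  yi <- y / step
  if (abs(yi - round(yi)) > 1e-9 || y < 0 || y > params$Y_max)
    stop("hypothermia depth must be a grid node in [0, Y_max], got ", y,
         call. = FALSE)
  as.integer(round(yi))
}

#' One-period body-temperature transition
#'
#' Behaviour 4 deepens hypothermia by one sigma step (clamped at `Y_max`),
#' behaviour 5 reduces it by `min(eta, y)` so the bird can never overshoot
#' normothermia, behaviour 6 holds depth constant.
#'
#' @param params a `winter_params` object.
#' @param y current depth, degC, on a grid node.
#' @param behaviour 4, 5 or 6.
#' @return the new depth in degC (exactly on a grid node).
#' @export
step_hypothermia <- function(params, y, behaviour) {
  if (!(length(behaviour) == 1L && behaviour %in% 4:6))
    stop("step_hypothermia applies to behaviours 4-6, got ", behaviour,
         call. = FALSE)
  d <- params$derived
  yi <- .y_index(params, y)
  n <- params$n_hypo_steps
  if (behaviour == 4L) {
    if (yi >= n) stop("behaviour 4 infeasible at maximal hypothermia", call. = FALSE)
    yi <- min(yi + d$sigma_nodes, n)
  } else if (behaviour == 5L) {
    if (yi <= 0L) stop("behaviour 5 infeasible for a normothermic bird", call. = FALSE)
    yi <- max(yi - d$sigma_nodes, 0L)
  } else {
    if (yi <= 0L) stop("behaviour 6 infeasible for a normothermic bird", call. = FALSE)
  }
  yi * d$hypo_step
}

#' Fat needed to rewarm from depth y
#'
#' A bird ending winter hypothermic must still fund its return to
#' normothermia: a pro-rated share of the extra warm-up cost, `(y/Y_max) C_WU`,
#' plus resting metabolism for each of the `ceiling(y/sigma)` rewarming
#' periods. `x_C(0) = 0`.
#'
#' @param params a `winter_params` object.
#' @param y depth in degC (vectorised; grid nodes).
#' @return required fat in kJ.
#' @export
warmup_fat_requirement <- function(params, y) {
  d <- params$derived
  vapply(y, function(yy) {
    yi <- .y_index(params, yy)
    n_steps <- ceiling(yi / d$sigma_nodes - 1e-9)
    (yy / params$Y_max) * params$C_WU + n_steps * d$C_RM_period
  }, numeric(1))
}
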