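# Model parameters: defaults, validation, per-period derivation.
#
# All energies are kJ, temperatures degrees C, time in 5-min periods unless a
# field name says "daily". Daily rates are the natural scale to parameterise
# (and the scale the literature reports); derive_per_period() converts them to
# the per-period quantities the solver consumes.

.param_defaults <- list(
  # -- state space ----------------------------------------------------------
  X_max              = 148,     # kJ, ceiling of fat reserves (4 g fat)
  n_fat_steps        = 100,     # fat grid intervals (101 nodes)
  fat_energy_density = 37,      # kJ per g fat
  lean_mass_g        = 11.2 - 12 / 37,  # so 12 kJ fat gives an 11.2 g bird
  Y_max              = 7,       # degC, maximal body-temperature depression
  n_hypo_steps       = 6,       # hypothermia grid intervals (must be a multiple
                                # of n_warmup_periods so transitions stay on nodes)
  n_warmup_periods   = 6,       # periods for a full rewarm from Y_max (30 min)
  epsilon            = 0.3,     # max fraction of resting expenditure saved
  normothermic_temp  = 42,      # degC, presentation only
  # -- calendar -------------------------------------------------------------
  D_days             = 100,
  periods_per_day    = 288,     # 5-min periods
  extra_periods      = 96,      # appended after the last midnight so the
                                # horizon ends at a daybreak
  daylight_start     = 96,      # period-of-day of daybreak (08:00)
  daylight_end       = 192,     # half-open: daylight = [96, 192), 8 h
  # -- energetics -----------------------------------------------------------
  G_daily            = c(80, 60),  # kJ gross gain per full foraging day, behaviours 1-2
  Delta              = 1,          # food-availability multiplier on gains
  C_RM_daily         = 45,         # kJ/day resting metabolism
  mu                 = c(2, 2, 0, 0, 0, 0),  # activity multipliers per behaviour
  gamma              = 1.2,        # bad-weather expenditure multiplier
  delta              = 0.8,        # gain retained when foraging is unsuccessful
  lambda             = c(0.8, 0.8, 1, 1, 1, 1),  # per-period foraging success prob
  # -- predation ------------------------------------------------------------
  beta_daily         = c(2.5e-3, 1.25e-3, 2.5e-4),  # daily risk, lean bird, behaviours 1-3
  beta_hypo_day      = 5e-2,    # daily risk, hypothermic in daylight
  beta_hypo_night    = 3.7e-4,  # daily risk, hypothermic (or resting) at night
  x_cr               = 37,      # kJ, critical fat above which risk accelerates
  alpha_exp          = 3,       # exponent of the mass-dependent acceleration
  # -- weather --------------------------------------------------------------
  p_GG               = 0.9983,  # per-period persistence of good weather
  p_BB               = 0.9965,  # per-period persistence of bad weather
  # -- winter end and variants ----------------------------------------------
  C_WU               = 0,       # kJ, extra total cost of a full rewarm (0 or 6)
  x_start            = 12,      # kJ fat at the forward-simulation start
  T_f_day            = 80,      # first day winter can end
  daytime_hypo_risk_mode = "constant_high",  # or "linear_eq14", "safe_as_rest"
  shallow_forage_limit   = NA_real_,  # degC; foraging allowed while y < limit
  interp_method          = "steffen"  # fat interpolation: "steffen" or "linear"
)

.ci_preset <- list(D_days = 20, n_fat_steps = 60, n_hypo_steps = 4,
                   n_warmup_periods = 4, T_f_day = 16)

#' Construct a validated parameter set
#'
#' Builds the full parameter list for the winter survival model, starting from
#' baseline values and applying any overrides, then validates every invariant
#' and attaches the derived per-period quantities (see [derive_per_period()]).
#'
#' @param ... named overrides of baseline parameters (e.g. `epsilon = 0.15`).
#' @param preset `"full"` for the 100-day baseline winter, `"ci"` for a small
#'   20-day winter (12 fat steps, 4 hypothermia steps) suitable for quick runs.
#' @return A `winter_params` list; derived per-period quantities are in the
#'   `derived` element.
#' @examples
#' p <- winter_params()
#' p$derived$C_RM_period  # 45/288 kJ
#' @export
winter_params <- function(..., preset = c("full", "ci")) {
  preset <- match.arg(preset)
  p <- .param_defaults
  if (preset == "ci") p[names(.ci_preset)] <- .ci_preset
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    p[names(over)] <- over
  }
  p <- validate_params(p)
  p <- derive_per_period(p)
  class(p) <- "winter_params"
  p
}

#' Load parameters from a YAML configuration file
#'
#' Reads a flat `key: value` YAML file; keys that are absent take their
#' baseline values. Command-line style `key=value` override strings may be
#' supplied on top (vector values comma-separated, e.g. `"G_daily=88,66"`).
#'
#' @param path path to a YAML file, or `NULL` for baseline defaults.
#' @param overrides character vector of `key=value` strings applied after the file.
#' @param preset passed to [winter_params()].
#' @return A validated `winter_params` object.
#' @export
load_params <- function(path = NULL, overrides = character(), preset = "full") {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) stop("configuration file must be a YAML mapping: ", path,
                            call. = FALSE)
  }
  for (ov in overrides) {
    kv <- regmatches(ov, regexpr("=", ov), invert = TRUE)[[1]]
    if (length(kv) != 2L || !nzchar(kv[1]))
      stop("malformed override (expected key=value): ", ov, call. = FALSE)
    cfg[[trimws(kv[1])]] <- .coerce_param(trimws(kv[1]), trimws(kv[2]))
  }
  unknown <- setdiff(names(cfg), names(.param_defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(winter_params, c(cfg, list(preset = preset)))
}

# coerce a "--set" string to the type of the default for that key
.coerce_param <- function(key, value) {
  if (!key %in% names(.param_defaults))
    stop("unknown configuration key: ", key, call. = FALSE)
  default <- .param_defaults[[key]]
  if (is.character(default)) return(value)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(parts))
  if (anyNA(num) && !all(toupper(parts) == "NA"))
    stop("configuration key ", key, " expects numeric value(s), got: ", value,
         call. = FALSE)
  num
}

#' Write a parameter set to a YAML file
#'
#' Serialises the user-settable fields (not the derived per-period quantities);
#' [load_params()] on the result reproduces an identical parameter set.
#'
#' @param params a `winter_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "winter_params"))
  keep <- params[names(.param_defaults)]
  yaml::write_yaml(keep, path)
  invisible(path)
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                   call. = FALSE)

#' @keywords internal
validate_params <- function(p) {
  num1 <- function(key) {
    v <- p[[key]]
    .assert(is.numeric(v) && length(v) == 1L && is.finite(v),
            paste0(key, " must be a single finite number"))
    v
  }
  for (k in setdiff(names(.param_defaults),
                    c("G_daily", "mu", "lambda", "beta_daily",
                      "daytime_hypo_risk_mode", "shallow_forage_limit",
                      "interp_method")))
    num1(k)
  .assert(is.numeric(p$G_daily) && length(p$G_daily) == 2L && all(p$G_daily > 0),
          "G_daily must be two positive gains (behaviours 1 and 2)")
  .assert(is.numeric(p$mu) && length(p$mu) == 6L && all(p$mu >= 0),
          "mu must be six non-negative activity multipliers")
  .assert(is.numeric(p$lambda) && length(p$lambda) == 6L &&
            all(p$lambda > 0 & p$lambda <= 1),
          "lambda must be six success probabilities in (0, 1]")
  .assert(is.numeric(p$beta_daily) && length(p$beta_daily) == 3L &&
            all(p$beta_daily >= 0 & p$beta_daily < 1),
          "beta_daily must be three daily hazards in [0, 1)")
  .assert(p$epsilon > 0 && p$epsilon <= 1, "epsilon must lie in (0, 1]")
  .assert(p$gamma >= 1, "gamma must be >= 1")
  .assert(p$delta > 0 && p$delta <= 1, "delta must lie in (0, 1]")
  .assert(p$p_GG > 0 && p$p_GG < 1, "p_GG must lie in (0, 1)")
  .assert(p$p_BB > 0 && p$p_BB < 1, "p_BB must lie in (0, 1)")
  .assert(p$X_max > 0, "X_max must be positive")
  .assert(p$n_fat_steps >= 2 && p$n_fat_steps == round(p$n_fat_steps),
          "n_fat_steps must be an integer >= 2")
  .assert(p$Y_max > 0, "Y_max must be positive")
  .assert(p$n_hypo_steps >= 1 && p$n_hypo_steps == round(p$n_hypo_steps),
          "n_hypo_steps must be a positive integer")
  .assert(p$n_warmup_periods >= 1 &&
            p$n_warmup_periods == round(p$n_warmup_periods),
          "n_warmup_periods must be a positive integer")
  .assert(p$n_hypo_steps %% p$n_warmup_periods == 0,
          "n_hypo_steps must be a multiple of n_warmup_periods so that body-temperature transitions land on grid nodes")
  .assert(p$D_days >= 1 && p$D_days == round(p$D_days), "D_days must be a positive integer")
  .assert(p$periods_per_day >= 2 && p$periods_per_day == round(p$periods_per_day),
          "periods_per_day must be an integer >= 2")
  .assert(p$daylight_start >= 0 && p$daylight_end <= p$periods_per_day &&
            p$daylight_start < p$daylight_end,
          "daylight window [daylight_start, daylight_end) must lie inside one day")
  .assert(p$daylight_end - p$daylight_start < p$periods_per_day,
          "there must be at least one night period")
  .assert(p$extra_periods >= 0 &&
            p$extra_periods %% p$periods_per_day == p$daylight_start,
          "extra_periods must place the final period at a daybreak (extra_periods mod periods_per_day == daylight_start)")
  .assert(p$T_f_day >= 1 && p$T_f_day <= p$D_days,
          "T_f_day must lie in [1, D_days]")
  .assert(p$C_WU >= 0, "C_WU must be non-negative")
  .assert(p$x_start > 0 && p$x_start <= p$X_max, "x_start must lie in (0, X_max]")
  .assert(p$x_cr > 0 && p$x_cr <= p$X_max, "x_cr must lie in (0, X_max]")
  .assert(p$alpha_exp > 0, "alpha_exp must be positive")
  .assert(p$C_RM_daily > 0, "C_RM_daily must be positive")
  .assert(p$fat_energy_density > 0, "fat_energy_density must be positive")
  .assert(is.character(p$daytime_hypo_risk_mode) &&
            p$daytime_hypo_risk_mode %in%
              c("constant_high", "linear_eq14", "safe_as_rest"),
          "daytime_hypo_risk_mode must be one of constant_high, linear_eq14, safe_as_rest")
  .assert(is.character(p$interp_method) &&
            p$interp_method %in% c("steffen", "linear"),
          "interp_method must be \"steffen\" or \"linear\"")
  .assert(length(p$shallow_forage_limit) == 1L &&
            (is.na(p$shallow_forage_limit) ||
               (p$shallow_forage_limit > 0 && p$shallow_forage_limit <= p$Y_max)),
          "shallow_forage_limit must be NA or a depth in (0, Y_max]")
  p
}

#' Derive per-period quantities from daily rates
#'
#' Daily energies divide evenly over the periods they accrue in (resting
#' metabolism over the whole day, foraging gains over daylight). Daily
#' predation hazards convert by compounding, `b_period = 1 - (1 - b_daily)^(1/n)`
#' over the `n` daylight (or night) periods, so that per-period survival factors
#' multiply back exactly to the daily value.
#'
#' @param params a (validated) parameter list.
#' @return `params` with a `derived` element holding per-period rates, grid
#'   steps, the winter-end hazard schedule and bookkeeping indices.
#' @export
derive_per_period <- function(params) {
  p <- params
  ppd <- p$periods_per_day
  n_day <- p$daylight_end - p$daylight_start
  n_night <- ppd - n_day
  n_total <- p$D_days * ppd + p$extra_periods  # horizon T (periods 0..T)

  d <- list(
    n_daylight       = n_day,
    n_night          = n_night,
    n_periods_total  = n_total,
    C_RM_period      = p$C_RM_daily / ppd,
    G_period         = p$G_daily * p$Delta / n_day,
    # G_daily is the expected gross gain over a full foraging day, inclusive of
    # the success lottery; the realised gain in a successful period is
    # therefore G_period / (lambda + (1-lambda) delta)
    G_succ_period    = p$G_daily * p$Delta / n_day /
      (p$lambda[1:2] + (1 - p$lambda[1:2]) * p$delta),
    beta_day_period  = 1 - (1 - p$beta_daily)^(1 / n_day),
    beta_night_rest_period = 1 - (1 - p$beta_daily[3])^(1 / n_night),
    beta_hypo_day_period   = 1 - (1 - p$beta_hypo_day)^(1 / n_day),
    beta_hypo_night_period = 1 - (1 - p$beta_hypo_night)^(1 / n_night),
    fat_step         = p$X_max / p$n_fat_steps,
    hypo_step        = p$Y_max / p$n_hypo_steps,
    sigma_nodes      = p$n_hypo_steps / p$n_warmup_periods,
    sigma_C          = p$Y_max / p$n_warmup_periods,
    C_WU_per_period  = p$C_WU / p$n_warmup_periods,
    T_f_period       = (p$T_f_day - 1) * ppd,
    start_period     = p$daylight_start  # day-1 daybreak
  )
  # foraging allowed from y-nodes strictly below the shallow limit (baseline:
  # only the normothermic node)
  hypo_values <- seq(0, p$Y_max, length.out = p$n_hypo_steps + 1)
  d$shallow_nodes <- if (is.na(p$shallow_forage_limit)) 1L else
    as.integer(sum(hypo_values < p$shallow_forage_limit))
  # winter-end hazard: applied at daybreak periods only, uniform over the
  # candidate daybreaks from T_f to the horizon T inclusive
  cand <- seq(p$daylight_start, n_total, by = ppd)
  cand <- cand[cand >= d$T_f_period]
  end_p <- numeric(n_total + 1)
  end_p[cand + 1L] <- 1 / (length(cand) - seq_along(cand) + 1)
  d$end_daybreaks <- cand
  d$end_p <- end_p
  p$derived <- d
  p
}

#' @export
print.winter_params <- function(x, ...) {
  d <- x$derived
  cat("Winter survival model parameters\n")
  cat(sprintf("  winter: %d days x %d periods/day + %d extra = %d periods\n",
              x$D_days, x$periods_per_day, x$extra_periods, d$n_periods_total))
  cat(sprintf("  fat grid: [0, %g] kJ, %d steps (%.3g kJ); hypothermia: [0, %g] degC, %d steps\n",
              x$X_max, x$n_fat_steps, d$fat_step, x$Y_max, x$n_hypo_steps))
  cat(sprintf("  epsilon = %g, C_WU = %g kJ, Delta = %g, gamma = %g, delta = %g\n",
              x$epsilon, x$C_WU, x$Delta, x$gamma, x$delta))
  cat(sprintf("  weather persistence: p_GG = %g, p_BB = %g (per period)\n",
              x$p_GG, x$p_BB))
  cat(sprintf("  daytime hypothermia risk mode: %s\n", x$daytime_hypo_risk_mode))
  invisible(x)
}

# convenience: grams of body mass at a given fat load
#' Convert fat reserves (kJ) to body mass (g)
#'
#' Lean mass is constant; fat converts at `fat_energy_density` (37 kJ/g), so the
#' baseline start state of 12 kJ corresponds to an 11.2 g bird at dawn.
#'
#' @param params a `winter_params` object.
#' @param fat_kJ numeric vector of fat reserves in kJ.
#' @return body mass in grams.
#' @export
fat_to_mass <- function(params, fat_kJ) {
  params$lean_mass_g + fat_kJ / params$fat_energy_density
}
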