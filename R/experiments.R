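# Experiment drivers: parameter sweeps replicated from the study design.

#' Modify a parameter set
#'
#' Rebuilds (and re-validates, re-derives) a `winter_params` with the given
#' overrides applied to its user-settable fields.
#'
#' @param params a `winter_params` object.
#' @param ... named overrides.
#' @return a new `winter_params`.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "winter_params"))
  base <- params[names(.param_defaults)]
  over <- list(...)
  base[names(over)] <- over
  do.call(winter_params, base)
}

#' Winter survival as a function of the maximum hypothermic saving
#'
#' Re-solves the model for each maximum saving fraction and reads whole-winter
#' survival at the forward-start state. Because hypothermia is optional, the
#' curve is non-decreasing in the saving.
#'
#' @param params a `winter_params` object (its `epsilon` is ignored).
#' @param savings vector of saving fractions in `[0, 1]`; 0 disables
#'   hypothermia's benefit entirely (implemented as a vanishing saving).
#' @return data.frame with `saving` and `survival`.
#' @export
sweep_max_saving <- function(params, savings = seq(0, 0.3, by = 0.05)) {
  stopifnot(all(savings >= 0 & savings <= 1))
  survival <- vapply(savings, function(eps) {
    # epsilon = 0 exactly is outside the validated range; a vanishing saving
    # is equivalent (behaviours 4-6 then only cost risk and warm-up time)
    p2 <- update_params(params, epsilon = if (eps == 0) 1e-9 else eps)
    solve_policy(p2)$start_survival
  }, numeric(1))
  data.frame(saving = savings, survival = survival)
}

#' Food-availability sweep
#'
#' For each gain multiplier `Delta`, solves the model, forward-simulates a
#' cohort, and summarises the stabilized mid-winter day: dawn and dusk fat,
#' night-time hypothermia use, and the daylight time budget of foraging and
#' resting behaviours.
#'
#' @param params a `winter_params` object.
#' @param deltas gain multipliers (1 = baseline food availability).
#' @param n_birds,seed forwarded to [simulate_cohort()].
#' @param mid_day the day summarised (default: mid-winter).
#' @return data.frame per `Delta` with `dawn_fat_g`, `dusk_fat_g`,
#'   `night_hypo_fraction`, daylight fractions `frac_b1`..`frac_b3`, and
#'   cohort `survival`.
#' @export
sweep_delta <- function(params, deltas = seq(1, 1.5, by = 0.1),
                        n_birds = 1000, seed = 1, mid_day = NULL) {
  if (is.null(mid_day)) mid_day <- mid_winter_day(params)
  rows <- lapply(deltas, function(dd) {
    p2 <- update_params(params, Delta = dd)
    fit <- solve_policy(p2)
    ens <- simulate_cohort(fit, n_birds = n_birds, seed = seed,
                           record_days = c(mid_day - 1L, mid_day))
    sm <- summarize_day(ens, mid_day)
    dl <- sm[sm$daylight, ]
    t_dawn <- (mid_day - 1L) * p2$periods_per_day + p2$daylight_start
    cc <- .rec_cols(ens, t_dawn)
    al <- ens$alive[, cc] == 1L
    data.frame(
      Delta = dd,
      dawn_fat_g = mean(ens$fat[al, cc]) / p2$fat_energy_density,
      dusk_fat_g = dusk_fat(ens, mid_day),
      night_hypo_fraction = night_hypo_fraction(ens, mid_day),
      frac_b1 = mean(dl$frac_b1), frac_b2 = mean(dl$frac_b2),
      frac_b3 = mean(dl$frac_b3),
      survival = cohort_survival(ens)$survival
    )
  })
  do.call(rbind, rows)
}

#' Saving fraction below which night-time hypothermia is abandoned
#'
#' Scans the maximum saving downward on a grid and returns the largest value
#' at which the forward-simulated cohort uses no hypothermia at all during the
#' stabilized mid-winter night.
#'
#' @param params a `winter_params` object.
#' @param from top of the scan (default 0.30).
#' @param step scan decrement (default 0.01).
#' @param n_birds,seed forwarded to [simulate_cohort()].
#' @param mid_day the night summarised ends at this day's dawn.
#' @return the abandonment saving fraction (0 if hypothermia is used on the
#'   whole grid), with the scan table in attribute `"scan"`.
#' @export
find_abandonment_saving <- function(params, from = 0.30, step = 0.01,
                                    n_birds = 1000, seed = 1, mid_day = NULL) {
  if (is.null(mid_day)) mid_day <- mid_winter_day(params)
  grid <- seq(from, step, by = -step)
  rows <- list()
  found <- 0
  for (eps in grid) {
    p2 <- update_params(params, epsilon = eps)
    fit <- solve_policy(p2)
    ens <- simulate_cohort(fit, n_birds = n_birds, seed = seed,
                           record_days = c(mid_day - 1L, mid_day))
    fr <- night_hypo_fraction(ens, mid_day)
    rows[[length(rows) + 1L]] <- data.frame(saving = eps,
                                            night_hypo_fraction = fr)
    # NaN means no bird was alive to observe: not evidence of abandonment
    if (!is.nan(fr) && fr == 0) { found <- eps; break }
  }
  structure(found, scan = do.call(rbind, rows))
}

#' Default stabilized mid-winter day
#'
#' The policy's daily routine stabilizes within the first week of the forward
#' iteration; summaries default to the middle of the winter, well clear of
#' both the start transient and the end-of-winter window.
#'
#' @param params a `winter_params` object.
#' @return a day index.
#' @export
mid_winter_day <- function(params) {
  max(3L, min(params$D_days %/% 2L, params$T_f_day - 1L))
}

#' Write a reproducibility manifest
#'
#' Records the full parameter set, its MD5 fingerprint, the seed and software
#' versions alongside a run's outputs.
#'
#' @param path output JSON path.
#' @param params a `winter_params` object.
#' @param seed the seed used (or `NULL` for deterministic stages).
#' @param outputs character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed = NULL, outputs = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  write_params(params, tmp)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("winterbird")),
    r_version = R.version.string,
    seed = seed,
    params_md5 = unname(tools::md5sum(tmp)),
    params = params[names(.param_defaults)],
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
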