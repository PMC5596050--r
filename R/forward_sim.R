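# Monte Carlo forward simulation of a cohort following the optimal policy.

#' Simulate a cohort of birds following the optimal policy
#'
#' Each bird starts at the day-1 daybreak with `x_start` kJ of fat,
#' normothermic, in good weather, and each period looks up the optimal
#' behaviour (fat snapped to the nearest grid node), draws foraging success,
#' the weather transition, predation and — at candidate daybreaks — the end of
#' winter, then updates its state. Birds die by predation, by starvation
#' (fat reaching 0), or fail at winter's end if their fat cannot fund
#' rewarming. Every bird has its own RNG stream derived from the master seed,
#' so trajectories are invariant to cohort size.
#'
#' @param fit a `winter_policy` from [solve_policy()].
#' @param n_birds cohort size (1000 in the baseline experiments).
#' @param seed integer master seed.
#' @param record_days 1-based day indices for which full per-period states are
#'   recorded (day `D_days + 1` holds the final morning).
#' @return A `winter_cohort`: per-bird `outcome`
#'   (`survived`/`predation`/`starvation`/`end_unprepared`), `end_period`, and
#'   for recorded periods matrices `fat` (kJ), `y_idx` (depth nodes),
#'   `behaviour`, `weather` (0 good / 1 bad), `alive` (birds x periods).
#' @export
simulate_cohort <- function(fit, n_birds = 1000, seed = 1, record_days = integer(0)) {
  stopifnot(inherits(fit, "winter_policy"), n_birds >= 1)
  p <- fit$params; d <- p$derived
  record_days <- sort(unique(as.integer(record_days)))
  if (length(record_days) &&
      (min(record_days) < 1 || max(record_days) > p$D_days + 1L))
    stop("record_days out of range", call. = FALSE)
  record_ts <- unlist(lapply(record_days, function(dd)
    (dd - 1L) * p$periods_per_day + 0:(p$periods_per_day - 1L)))
  record_ts <- sort(record_ts[record_ts <= d$n_periods_total])
  if (is.null(record_ts)) record_ts <- integer(0)

  res <- cpp_simulate(.cpp_inputs(p), fit$policy, as.integer(n_birds),
                      as.numeric(seed), as.integer(record_ts),
                      p$x_start, as.integer(d$start_period))
  lab <- c("survived", "predation", "starvation", "end_unprepared")
  ens <- list(
    params = p, n_birds = as.integer(n_birds), seed = seed,
    record_days = record_days, record_ts = record_ts,
    outcome = factor(lab[res$outcome + 1L], levels = lab),
    end_period = res$end_period,
    fat = res$fat, y_idx = res$y, behaviour = res$behaviour,
    weather = res$weather, alive = res$alive
  )
  class(ens) <- "winter_cohort"
  ens
}

#' Cohort survival and mortality bookkeeping
#'
#' @param ens a `winter_cohort`.
#' @return list with outcome `counts` (summing to the cohort size) and the
#'   `survival` fraction.
#' @export
cohort_survival <- function(ens) {
  counts <- table(ens$outcome)
  list(counts = counts, survival = unname(counts["survived"]) / ens$n_birds)
}

.rec_cols <- function(ens, ts) {
  cols <- match(ts, ens$record_ts)
  if (anyNA(cols))
    stop("periods not recorded; pass the relevant day(s) via record_days= ",
         "when simulating", call. = FALSE)
  cols
}

# periods of the night that ends at dawn of `day` (evening of day-1 + morning
# of day), and that dawn period
.night_before_dawn <- function(params, day) {
  ppd <- params$periods_per_day
  t_dawn <- (day - 1L) * ppd + params$daylight_start
  list(ts = ((day - 2L) * ppd + params$daylight_end):(t_dawn - 1L),
       t_dawn = t_dawn)
}

#' Per-period summary of a recorded day
#'
#' @param ens a `winter_cohort`.
#' @param day a recorded day (1-based).
#' @return data.frame per period-of-day with the number of birds alive, mean
#'   and SD body mass (g), mean body temperature (degC below-normal depth
#'   subtracted from the normothermic 42), and the behaviour time budget.
#' @export
summarize_day <- function(ens, day) {
  p <- ens$params
  ts <- (day - 1L) * p$periods_per_day + 0:(p$periods_per_day - 1L)
  ts <- ts[ts <= p$derived$n_periods_total]
  cols <- .rec_cols(ens, ts)
  out <- lapply(seq_along(cols), function(j) {
    cc <- cols[j]
    al <- ens$alive[, cc] == 1L
    fat <- ens$fat[al, cc]
    yC <- ens$y_idx[al, cc] * p$derived$hypo_step
    beh <- ens$behaviour[al, cc]
    fr <- vapply(1:6, function(i) mean(beh == i, na.rm = TRUE), numeric(1))
    data.frame(period = ts[j], n_alive = sum(al),
               mean_mass_g = mean(fat_to_mass(p, fat)),
               sd_mass_g = stats::sd(fat_to_mass(p, fat)),
               mean_temp_C = p$normothermic_temp - mean(yC),
               frac_b1 = fr[1], frac_b2 = fr[2], frac_b3 = fr[3],
               frac_b4 = fr[4], frac_b5 = fr[5], frac_b6 = fr[6])
  })
  out <- do.call(rbind, out)
  out$period_of_day <- out$period %% p$periods_per_day
  out$daylight <- out$period_of_day >= p$daylight_start &
    out$period_of_day < p$daylight_end
  out
}

#' Mean dawn-to-dusk fat gain on a recorded day
#'
#' @param ens a `winter_cohort`.
#' @param day a recorded day.
#' @return mean fat gained between daybreak and dusk over birds alive the whole
#'   day, in grams.
#' @export
dawn_dusk_gain <- function(ens, day) {
  p <- ens$params
  t0 <- (day - 1L) * p$periods_per_day + p$daylight_start
  t1 <- (day - 1L) * p$periods_per_day + p$daylight_end
  cc <- .rec_cols(ens, c(t0, t1))
  al <- ens$alive[, cc[1]] == 1L & ens$alive[, cc[2]] == 1L
  mean(ens$fat[al, cc[2]] - ens$fat[al, cc[1]]) / p$fat_energy_density
}

#' Mean dusk fat load on a recorded day
#'
#' @param ens a `winter_cohort`.
#' @param day a recorded day.
#' @return mean fat at the dusk period over birds alive then, in grams.
#' @export
dusk_fat <- function(ens, day) {
  p <- ens$params
  t1 <- (day - 1L) * p$periods_per_day + p$daylight_end
  cc <- .rec_cols(ens, t1)
  al <- ens$alive[, cc] == 1L
  mean(ens$fat[al, cc]) / p$fat_energy_density
}

#' Fraction of night periods spent hypothermic
#'
#' Measured over the night that ends at dawn of `day` (the evening of the
#' previous day plus the morning hours of `day`), over birds alive in each
#' period.
#'
#' @param ens a `winter_cohort`.
#' @param day a recorded day whose preceding evening is also recorded.
#' @return fraction of alive-bird night periods with depth > 0.
#' @export
night_hypo_fraction <- function(ens, day) {
  nb <- .night_before_dawn(ens$params, day)
  cols <- .rec_cols(ens, nb$ts)
  al <- ens$alive[, cols] == 1L
  y <- ens$y_idx[, cols]
  mean(y[al] > 0)
}

#' Rewarming onset before dawn
#'
#' Scans backwards from the dawn of `day` along the preceding night and counts
#' the contiguous run of periods in which the modal behaviour of alive birds is
#' rewarming (behaviour 5).
#'
#' @param ens a `winter_cohort`.
#' @param day a recorded day whose preceding evening is also recorded.
#' @return onset of rewarming in minutes before daybreak (0 if the policy never
#'   rewarms in that night).
#' @export
warming_onset_minutes <- function(ens, day) {
  p <- ens$params
  nb <- .night_before_dawn(p, day)
  cols <- .rec_cols(ens, nb$ts)
  run <- 0L
  for (j in rev(seq_along(cols))) {
    cc <- cols[j]
    al <- ens$alive[, cc] == 1L
    beh <- ens$behaviour[al, cc]
    beh <- beh[!is.na(beh)]
    if (!length(beh)) break
    counts <- tabulate(beh, nbins = 6L)
    if (which.max(counts) == 5L) run <- run + 1L else break
  }
  run * (24 * 60 / p$periods_per_day)
}

#' Export recorded trajectories as a data frame
#'
#' @param ens a `winter_cohort`.
#' @param birds bird indices to include (default: all).
#' @return long data.frame: `bird`, `day`, `period`, `period_of_day`,
#'   `fat_kJ`, `mass_g`, `temp_C`, `behaviour`, `weather`, `alive`.
#' @export
trajectory_frame <- function(ens, birds = seq_len(ens$n_birds)) {
  p <- ens$params
  nt <- length(ens$record_ts)
  out <- data.frame(
    bird = rep(birds, times = nt),
    period = rep(ens$record_ts, each = length(birds))
  )
  idx <- cbind(rep(birds, times = nt), rep(seq_len(nt), each = length(birds)))
  out$day <- out$period %/% p$periods_per_day + 1L
  out$period_of_day <- out$period %% p$periods_per_day
  out$fat_kJ <- ens$fat[idx]
  out$mass_g <- fat_to_mass(p, out$fat_kJ)
  out$temp_C <- p$normothermic_temp - ens$y_idx[idx] * p$derived$hypo_step
  out$behaviour <- ens$behaviour[idx]
  out$weather <- c("G", "B")[ens$weather[idx] + 1L]
  out$alive <- ens$alive[idx] == 1L
  out
}

#' @export
print.winter_cohort <- function(x, ...) {
  s <- cohort_survival(x)
  cat(sprintf("Forward-simulated cohort: %d birds, seed %s\n",
              x$n_birds, format(x$seed)))
  print(s$counts)
  cat(sprintf("  winter survival: %.3f\n", s$survival))
  invisible(x)
}
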