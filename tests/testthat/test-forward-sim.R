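test_that("with no stochasticity every bird follows the same trajectory", {
  p <- deterministic_params()
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 5, seed = 42, record_days = c(5, 6))
  # days 5-6 are before the end window, so no bird has been censored
  expect_true(all(ens$alive == 1))
  for (b in 2:5) {
    expect_equal(ens$fat[b, ], ens$fat[1, ])
    expect_equal(ens$y_idx[b, ], ens$y_idx[1, ])
    expect_equal(ens$behaviour[b, ], ens$behaviour[1, ])
  }
})

test_that("cohort bookkeeping conserves the number of birds", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 500, seed = 9)
  s <- cohort_survival(ens)
  expect_equal(sum(s$counts), 500)
  expect_true(all(names(s$counts) ==
                    c("survived", "predation", "starvation", "end_unprepared")))
  expect_equal(s$survival, unname(s$counts["survived"]) / 500)
  # same seed reproduces; bird streams are independent of cohort size
  ens2 <- simulate_cohort(fit, n_birds = 500, seed = 9)
  expect_identical(ens$outcome, ens2$outcome)
  ens3 <- simulate_cohort(fit, n_birds = 100, seed = 9)
  expect_identical(ens3$outcome, ens$outcome[1:100])
})

test_that("dead birds stay dead and states stay legal while alive", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 300, seed = 4,
                         record_days = c(10, 11))
  alive <- ens$alive == 1
  expect_true(all(ens$fat[alive] > 0))
  expect_true(all(ens$fat[alive] <= p$X_max + 1e-9))
  expect_true(all(ens$y_idx[alive] >= 0 & ens$y_idx[alive] <= p$n_hypo_steps))
  # alive flags never flip back on within the recorded window
  flips <- apply(ens$alive, 1, function(a) any(diff(a) > 0))
  expect_false(any(flips))
  # recorded behaviours respect the masks: foraging only in daylight,
  # normothermic
  pod <- ens$record_ts %% p$periods_per_day
  is_day <- pod >= p$daylight_start & pod < p$daylight_end
  forage <- !is.na(ens$behaviour) & ens$behaviour <= 2
  expect_true(all(ens$y_idx[forage] == 0))
  expect_true(all(rep(is_day, each = nrow(forage))[forage]))
})

test_that("forward survival agrees with the backward value at the start", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 1000, seed = 21)
  s <- cohort_survival(ens)$survival
  se <- sqrt(s * (1 - s) / 1000)
  expect_lt(abs(s - fit$start_survival), 3 * se)
})

test_that("daily summaries aggregate the recorded states", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 50, seed = 2, record_days = c(9, 10))
  sm <- summarize_day(ens, 10)
  expect_equal(nrow(sm), p$periods_per_day)
  expect_true(all(sm$n_alive <= 50))
  fr <- sm[, paste0("frac_b", 1:6)]
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  expect_true(all(sm$mean_temp_C <= p$normothermic_temp + 1e-9))
  # a one-bird ensemble's summary is that bird's trajectory
  e1 <- simulate_cohort(fit, n_birds = 1, seed = 2, record_days = c(9, 10))
  s1 <- summarize_day(e1, 10)
  tf <- trajectory_frame(e1)
  tf <- tf[tf$day == 10 & tf$alive, ]
  expect_equal(s1$mean_mass_g[s1$n_alive == 1],
               tf$mass_g[match(s1$period[s1$n_alive == 1], tf$period)])
  # dawn-dusk gain: mean fat change over daylight, in grams
  t0 <- 9L * p$periods_per_day + p$daylight_start
  t1 <- 9L * p$periods_per_day + p$daylight_end
  i0 <- match(t0, ens$record_ts); i1 <- match(t1, ens$record_ts)
  both <- ens$alive[, i0] == 1 & ens$alive[, i1] == 1
  expect_equal(dawn_dusk_gain(ens, 10),
               mean(ens$fat[both, i1] - ens$fat[both, i0]) / 37)
  expect_error(dawn_dusk_gain(ens, 3), "not recorded")
})

test_that("night metrics capture hypothermia use and rewarming onset", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p)
  ens <- simulate_cohort(fit, n_birds = 200, seed = 6, record_days = c(9, 10))
  fr <- night_hypo_fraction(ens, 10)
  expect_true(fr >= 0 && fr <= 1)
  on <- warming_onset_minutes(ens, 10)
  expect_true(on >= 0)
  expect_equal(on %% 5, 0)
  # at the ci preset's 4-step lattice a full rewarm takes 4 periods = 20 min
  if (fr > 0.9) expect_equal(on, 20)
})
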