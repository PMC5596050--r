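test_that("baseline defaults match the study parameterisation", {
  # an empty config file falls back to baseline everywhere
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  p <- load_params(empty)
  expect_equal(p$X_max, 148)
  expect_equal(p$n_fat_steps, 100)
  expect_equal(p$Y_max, 7)
  expect_equal(p$epsilon, 0.3)
  expect_equal(p$C_WU, 0)
  expect_equal(p$x_start, 12)
  expect_equal(p$G_daily, c(80, 60))
  expect_equal(p$C_RM_daily, 45)
  expect_equal(p$p_GG, 0.9983)
  expect_equal(p$p_BB, 0.9965)
  expect_identical(p[names(winterbird:::.param_defaults)],
                   winter_params()[names(winterbird:::.param_defaults)])
})

test_that("overrides apply singly and bad configs are rejected by key", {
  base <- winter_params()
  p <- load_params(NULL, overrides = "epsilon=0.15")
  expect_equal(p$epsilon, 0.15)
  unchanged <- setdiff(names(winterbird:::.param_defaults), "epsilon")
  expect_identical(p[unchanged], base[unchanged])
  # vector override
  p2 <- load_params(NULL, overrides = "G_daily=88,66")
  expect_equal(p2$G_daily, c(88, 66))

  expect_error(winter_params(epsilon = 1.5), "epsilon")
  expect_error(winter_params(gamma = 0.9), "gamma")
  expect_error(winter_params(nonsense = 1), "unknown parameter")
  expect_error(load_params(NULL, overrides = "epsilon:0.2"), "key=value")
  expect_error(load_params(NULL, overrides = "epsilon=abc"), "epsilon")
  cfg <- tempfile(fileext = ".yaml")
  writeLines("not_a_key: 3", cfg)
  expect_error(load_params(cfg), "not_a_key")
})

test_that("per-period derivation divides energies and compounds hazards", {
  p <- winter_params()
  d <- p$derived
  expect_equal(d$C_RM_period, 45 / 288)
  expect_equal(d$G_period[1], 80 / 96)
  expect_equal(d$n_daylight, 96)
  expect_equal(d$n_night, 192)
  expect_equal(d$n_periods_total, 288 * 100 + 96)
  # a 20% food increase raises the expected daily gross gain from 80 to 96 kJ
  p12 <- update_params(p, Delta = 1.2)
  expect_equal(p12$derived$G_period[1] * 96, 96)
  expect_equal(p12$derived$G_period[2] * 96, 72)
  # expected gain inclusive of the success lottery equals the daily figure
  lam <- p$lambda[1]
  expect_equal(d$G_succ_period[1] * (lam + (1 - lam) * p$delta) * 96, 80)

  # compounding round-trip to 1e-12: per-period survival factors multiply
  # back to the daily hazard
  expect_equal((1 - d$beta_day_period)^96, 1 - p$beta_daily, tolerance = 1e-12)
  expect_equal((1 - d$beta_hypo_day_period)^96, 1 - p$beta_hypo_day,
               tolerance = 1e-12)
  expect_equal((1 - d$beta_hypo_night_period)^192, 1 - p$beta_hypo_night,
               tolerance = 1e-12)
  expect_equal((1 - d$beta_night_rest_period)^192, 1 - p$beta_daily[3],
               tolerance = 1e-12)
})

test_that("parameter files round-trip", {
  p <- winter_params(epsilon = 0.22, C_WU = 6, G_daily = c(70, 55),
                     daytime_hypo_risk_mode = "linear_eq14")
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- load_params(f)
  keys <- names(winterbird:::.param_defaults)
  expect_equal(p2[keys], p[keys])
})
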