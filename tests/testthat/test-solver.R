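test_that("behaviour masks follow the physiological rules", {
  p <- winter_params()
  day <- 100; night <- 10
  expect_equal(feasible_behaviours(p, 0, day), c(1, 2, 3, 4))
  expect_equal(feasible_behaviours(p, 0, night), c(3, 4))
  expect_equal(feasible_behaviours(p, p$derived$hypo_step, day), c(4, 5, 6))
  expect_equal(feasible_behaviours(p, p$Y_max, day), c(5, 6))
  expect_equal(feasible_behaviours(p, p$Y_max, night), c(5, 6))
  # shallow-forage variant: foraging allowed below a 2 degC depression
  ps <- winter_params(shallow_forage_limit = 2)
  expect_equal(feasible_behaviours(ps, ps$derived$hypo_step, day),
               c(1, 2, 4, 5, 6))
  expect_equal(feasible_behaviours(ps, 2 * ps$derived$hypo_step, day),
               c(4, 5, 6))
})

test_that("a one-period horizon reduces to the terminal reward", {
  p <- toy_params(C_WU = 1)
  fit <- solve_policy(p, keep_periods = "all")
  g <- build_grid(p)
  TT <- p$derived$n_periods_total
  xC <- warmup_fat_requirement(p, g$hypo_values)
  for (yi in seq_along(g$hypo_values)) for (wi in 1:2) {
    expect_equal(fit$F_keep[, yi, wi, TT + 1],
                 as.numeric(g$fat_values > 0 & g$fat_values >= xC[yi]))
  }
})

test_that("backward induction equals the compositional reference solver", {
  # several toy configurations: warm-up cost, risk variants, both
  # interpolants, shallow foraging
  cfgs <- list(
    list(),
    list(C_WU = 1),
    list(daytime_hypo_risk_mode = "linear_eq14"),
    list(daytime_hypo_risk_mode = "safe_as_rest", interp_method = "linear"),
    list(shallow_forage_limit = 1.5, epsilon = 0.12)
  )
  for (cfg in cfgs) {
    p <- do.call(toy_params, cfg)
    fit <- solve_policy(p, keep_periods = "all")
    ref <- oracle_solve(p)
    TT <- p$derived$n_periods_total
    expect_equal(as.numeric(fit$F_keep),
                 as.numeric(ref$F), tolerance = 1e-10)
    # the stored policy attains the reference value wherever survival is
    # still possible (ties may differ in label, never in value)
    for (t in 0:(TT - 1)) {
      pe <- end_probability(p, t)
      Fn <- ref$F[, , , t + 2]
      g <- build_grid(p)
      for (wi in 1:2) for (yi in seq_along(g$hypo_values)) {
        for (ki in 2:length(g$fat_values)) {
          i <- as.integer(fit$policy[ki, yi, wi, t + 1])
          v <- expected_value(p, Fn, i, g$fat_values[ki], g$hypo_values[yi],
                              c("G", "B")[wi], t)
          val <- if (pe > 0)
            pe * terminal_reward(p, g$fat_values[ki], g$hypo_values[yi], t) +
              (1 - pe) * v else v
          expect_equal(val, ref$F[ki, yi, wi, t + 1], tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("the value function is a probability and zero at exhausted reserves", {
  p <- winter_params(preset = "ci")
  fit <- solve_policy(p, keep_periods = c(0, 96, 2000))
  expect_true(all(fit$F_keep >= 0 & fit$F_keep <= 1))
  expect_true(all(fit$F_keep[1, , , ] == 0))
  expect_true(all(is.finite(fit$F_keep)))
  # stored behaviours always respect the feasibility mask
  g <- build_grid(p)
  set.seed(2)
  for (rep in 1:40) {
    t <- sample(0:(p$derived$n_periods_total - 1), 1)
    yi <- sample(seq_along(g$hypo_values), 1)
    ki <- sample(seq_along(g$fat_values), 1)
    wi <- sample(1:2, 1)
    i <- as.integer(fit$policy[ki, yi, wi, t + 1])
    expect_true(i %in% feasible_behaviours(p, g$hypo_values[yi], t))
  }
})

test_that("optional hypothermia means survival is monotone in the saving", {
  p <- winter_params(preset = "ci")
  sv <- sweep_max_saving(p, savings = c(0, 0.1, 0.2, 0.3))
  expect_true(all(diff(sv$survival) >= -1e-12))
  expect_true(all(sv$survival >= 0 & sv$survival <= 1))
})

test_that("policy and value tables export coherently", {
  p <- toy_params()
  fit <- solve_policy(p, keep_periods = "all")
  pf <- policy_frame(fit, days = 1)
  expect_equal(nrow(pf), 5 * 3 * 2 * 6)
  expect_true(all(pf$behaviour %in% 1:6))
  vf <- value_frame(fit)
  expect_true(all(vf$F >= 0 & vf$F <= 1))
  f <- tempfile(fileext = ".csv")
  write_policy_csv(fit, f, days = 1)
  expect_equal(nrow(utils::read.csv(f)), nrow(pf))
  # optimal_behaviour agrees with the stored array
  expect_equal(optimal_behaviour(fit, p$x_start, 0, "G", p$derived$start_period),
               as.integer(fit$policy[round(p$x_start / p$derived$fat_step) + 1,
                                     1, 1, p$derived$start_period + 1]))
})
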