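# Small fixtures built in code.

# A tiny 2-day winter (6 periods/day, 2 daylight) small enough for the
# reference solver to sweep exhaustively, but exercising every model piece:
# daylight window, end-of-winter daybreaks, hypothermia lattice, weather.
toy_params <- function(...) {
  winter_params(
    X_max = 6, n_fat_steps = 4, fat_energy_density = 37, lean_mass_g = 10,
    Y_max = 2, n_hypo_steps = 2, n_warmup_periods = 2, epsilon = 0.3,
    D_days = 2, periods_per_day = 6, extra_periods = 2,
    daylight_start = 2, daylight_end = 4,
    G_daily = c(4, 3), Delta = 1, C_RM_daily = 3,
    gamma = 1.2, delta = 0.8,
    beta_daily = c(0.02, 0.01, 0.002),
    beta_hypo_day = 0.2, beta_hypo_night = 0.003,
    x_cr = 2, alpha_exp = 3, p_GG = 0.9, p_BB = 0.8,
    C_WU = 0, x_start = 3, T_f_day = 2,
    ...
  )
}

# parameters with every source of stochasticity and hazard switched off
deterministic_params <- function(...) {
  winter_params(
    preset = "ci",
    lambda = c(1, 1, 1, 1, 1, 1),
    beta_daily = c(0, 0, 0),
    beta_hypo_day = 0, beta_hypo_night = 0,
    p_GG = 1 - 1e-12, p_BB = 1 - 1e-12,
    ...
  )
}
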