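# Reference solver used as an independent oracle for the C++ backward
# induction: a plain R sweep over every state and period that enumerates the
# feasible behaviours one by one through the compositional model functions
# (fat_transition, predation_hazard, step_hypothermia, interpolate_value,
# end_probability, terminal_reward). Only usable on toy-sized models.
oracle_solve <- function(params) {
  d <- params$derived
  grid <- build_grid(params)
  nf <- length(grid$fat_values)
  ny <- length(grid$hypo_values)
  TT <- d$n_periods_total
  xC <- warmup_fat_requirement(params, grid$hypo_values)
  F <- array(NA_real_, c(nf, ny, 2, TT + 1))
  pol <- array(NA_integer_, c(nf, ny, 2, TT))
  for (yi in seq_len(ny)) for (wi in 1:2)
    F[, yi, wi, TT + 1] <- as.numeric(grid$fat_values > 0 &
                                        grid$fat_values >= xC[yi])
  for (t in (TT - 1):0) {
    Fn <- F[, , , t + 2]
    pe <- end_probability(params, t)
    for (wi in 1:2) for (yi in seq_len(ny)) {
      y <- grid$hypo_values[yi]
      feas <- feasible_behaviours(params, y, t)
      for (ki in seq_len(nf)) {
        x <- grid$fat_values[ki]
        best <- -1; best_beta <- 2; best_i <- 0L
        for (i in feas) {
          v <- expected_value(params, Fn, i, x, y, c("G", "B")[wi], t)
          y2 <- if (i >= 4L) step_hypothermia(params, y, i) else y
          bz <- predation_hazard(params, i, x, y2, t)
          if (v > best || (v == best && bz < best_beta)) {
            best <- v; best_beta <- bz; best_i <- i
          }
        }
        val <- if (pe > 0) pe * terminal_reward(params, x, y, t) +
          (1 - pe) * best else best
        if (ki == 1L) val <- 0  # exhausted reserves are lethal
        F[ki, yi, wi, t + 1] <- val
        pol[ki, yi, wi, t + 1] <- best_i
      }
    }
  }
  list(F = F, policy = pol)
}
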