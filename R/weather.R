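# Two-state Markov weather chain.
#
# The only effect of bad weather is a 20% higher energy expenditure; the chain
# exists to inject realistic environmental unpredictability. Per-period
# persistences 0.9983 (good) and 0.9965 (bad) give a 61.3% chance that good
# weather lasts 24 h and 36.4% that bad weather does.

#' Weather transition matrix
#'
#' @param params a `winter_params` object.
#' @return 2x2 matrix with rows/cols `G`, `B`; rows sum to 1.
#' @export
weather_matrix <- function(params) {
  m <- matrix(c(params$p_GG, 1 - params$p_GG,
                1 - params$p_BB, params$p_BB),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("G", "B"), c("G", "B")))
  m
}

#' Probability that weather persists unchanged for n periods
#'
#' @param params a `winter_params` object.
#' @param state `"G"` or `"B"`.
#' @param n_periods number of consecutive periods (>= 0).
#' @return `p_ss^n`.
#' @export
persistence_probability <- function(params, state = c("G", "B"), n_periods) {
  state <- match.arg(state)
  stopifnot(n_periods >= 0)
  p <- if (state == "G") params$p_GG else params$p_BB
  p^n_periods
}

#' Stationary distribution of the weather chain
#'
#' @param params a `winter_params` object.
#' @return named probabilities of `G` and `B`.
#' @export
stationary_weather <- function(params) {
  qG <- 1 - params$p_GG
  qB <- 1 - params$p_BB
  c(G = qB / (qG + qB), B = qG / (qG + qB))
}

#' Sample a weather path
#'
#' @param params a `winter_params` object.
#' @param start starting state, `"G"` or `"B"`.
#' @param n_periods path length.
#' @param seed integer seed (the R RNG state is restored afterwards).
#' @return character vector of states of length `n_periods`, beginning at
#'   `start`.
#' @export
sample_weather <- function(params, start = c("G", "B"), n_periods, seed = NULL) {
  start <- match.arg(start)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  u <- stats::runif(n_periods - 1)
  path <- character(n_periods)
  path[1] <- start
  for (k in seq_len(n_periods - 1)) {
    p_stay <- if (path[k] == "G") params$p_GG else params$p_BB
    path[k + 1] <- if (u[k] < p_stay) path[k] else setdiff(c("G", "B"), path[k])
  }
  path
}
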