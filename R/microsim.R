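#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n` independent patients through the same per-cycle transition
#' matrices the cohort engine uses, drawing each transition at random. The
#' occupancy proportions converge to the deterministic cohort trace as `n`
#' grows, which makes this the sampling-based cross-check for the cohort
#' propagation.
#'
#' @param params an `af_params` object.
#' @param arm `"screening"` or `"no_screening"`.
#' @param lifetable an `af_life_table`.
#' @param n number of simulated individuals.
#' @param seed RNG seed.
#' @param n_cycles number of cycles to simulate (default: to `max_age`).
#' @return list with `occupancy` (cycles x 8 matrix of proportions,
#'   row 1 = initial state) and `n`.
#' @export
microsimulate <- function(params, arm = "screening", lifetable, n = 1e5,
                          seed = 1, n_cycles = NULL) {
  stopifnot(inherits(params, "af_params"))
  cy <- params$cycle
  if (is.null(n_cycles)) {
    n_cycles <- floor((cy$max_age - cy$start_age) / cy$cycle_length) + 1L
  }
  sch <- cycle_schedule(params, arm, lifetable, n_cycles)

  set.seed(seed)
  states <- af_states()
  occ <- matrix(0, n_cycles + 1L, 8, dimnames = list(NULL, states))
  state <- rep(1L, n)
  occ[1, ] <- tabulate(state, 8) / n
  for (k in seq_len(n_cycles)) {
    P <- transition_from_schedule(sch, k)
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    nxt <- state
    for (s in unique(state)) {
      i <- state == s
      nxt[i] <- findInterval(u[i], cum[s, ], left.open = TRUE) + 1L
    }
    state <- nxt
    occ[k + 1L, ] <- tabulate(state, 8) / n
    if (all(state >= 5L)) {
      occ <- occ[seq_len(k + 1L), , drop = FALSE]
      break
    }
  }
  list(occupancy = occ, n = n)
}

#' Transition matrix for cycle k of a precomputed schedule
#' @noRd
transition_from_schedule <- function(sch, i) {
  states <- af_states()
  P <- matrix(0, 8, 8, dimnames = list(states, states))
  res <- sch$residual_af[i]
  P[1, 2] <- sch$p_nf_stroke[i]
  P[1, 5] <- sch$p_fatal_stroke[i]
  P[1, 7] <- sch$p_fatal_bleed[i]
  P[1, 8] <- res * sch$q_af[i]
  if (sch$bleed_tunnel) {
    P[1, 4] <- sch$p_nf_bleed[i]
    P[1, 1] <- res * (1 - sch$q_af[i])
  } else {
    P[1, 1] <- res * (1 - sch$q_af[i]) + sch$p_nf_bleed[i]
  }
  P[2, 6] <- sch$p_psd
  P[2, 8] <- (1 - sch$p_psd) * sch$q_as[i]
  P[2, 3] <- (1 - sch$p_psd) * (1 - sch$q_as[i])
  P[3, 6] <- sch$p_psd
  P[3, 8] <- (1 - sch$p_psd) * sch$q_ps[i]
  P[3, 3] <- (1 - sch$p_psd) * (1 - sch$q_ps[i])
  P[4, 8] <- sch$q_ab[i]
  P[4, 1] <- 1 - sch$q_ab[i]
  for (s in 5:8) P[s, s] <- 1
  P
}
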