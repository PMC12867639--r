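# Inequity-averse utility and introspection dynamics.
#
# Players evaluate round outcomes with
#   u_i = pi_i - beta * |c1 - c2| / max(e1, e2) - gamma * |c1/e1 - c2/e2|,
# penalizing unequal absolute contributions (weight beta) and unequal
# relative contributions (weight gamma). Strategy revision follows
# introspection dynamics: a randomly chosen player compares their realized
# block utility against the block utility a random alternative strategy
# would have realized (coplayer unchanged), and switches with the logistic
# probability phi(u_alt, u_cur) = 1 / (1 + exp(-s (u_alt - u_cur))).

#' Inequity-aversion parameters
#'
#' @param beta Nonnegative weight on unequal absolute contributions.
#' @param gamma Nonnegative weight on unequal relative contributions.
#' @return A `utility_params` list.
#' @export
utility_params <- function(beta = 0, gamma = 0) {
  stopifnot(beta >= 0, gamma >= 0)
  structure(list(beta = beta, gamma = gamma), class = "utility_params")
}

#' Per-round inequity-averse utility
#'
#' With `beta = gamma = 0` the utility equals the material payoff.
#'
#' @param spec A two-player `pgg_game`.
#' @param params A [utility_params()] object.
#' @param profile Integer contribution vector `c(c1, c2)`.
#' @return Numeric utility vector for the two players.
#' @export
round_utility <- function(spec, params, profile) {
  if (spec$n != 2) stop("round_utility() supports two-player games only")
  c_i <- check_profile(spec, profile)
  pi_i <- payoffs(spec, c_i)
  pen <- params$beta * abs(c_i[1] - c_i[2]) / max(spec$e) +
    params$gamma * abs(c_i[1] / spec$e[1] - c_i[2] / spec$e[2])
  pi_i - pen
}

#' Block utility of a play trace
#'
#' @param spec A two-player `pgg_game`.
#' @param params A [utility_params()] object.
#' @param trace A `pgg_trace` from [rollout()].
#' @param aggregation `"sum"` (default: the realized total utility over the
#'   block, the literal reading of comparing realized multi-round utilities)
#'   or `"mean"`.
#' @return Numeric utility vector for the two players.
#' @export
block_utility <- function(spec, params, trace, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  rounds <- nrow(trace$contributions)
  if (is.null(rounds) || rounds == 0) stop("empty trace")
  u <- rowSums(vapply(seq_len(rounds), function(t)
    round_utility(spec, params, trace$contributions[t, ]), numeric(2)))
  if (aggregation == "mean") u / rounds else u
}

#' Logistic (Fermi) switch probability
#'
#' `phi(u_alt, u_cur) = 1 / (1 + exp(-s (u_alt - u_cur)))`; equals 1/2 when
#' the utilities tie or when `s = 0`, and satisfies
#' `phi(a, b) + phi(b, a) = 1`. Overflow-safe for large `|s * delta|`.
#'
#' @param u_alt,u_cur Utilities of the alternative and current strategy.
#' @param s Selection strength, `>= 0`.
#' @return Switch probability in `(0, 1)` (vectorized).
#' @export
switch_probability <- function(u_alt, u_cur, s) {
  stopifnot(all(s >= 0))
  stats::plogis(s * (u_alt - u_cur))
}

#' Configuration for an introspection-dynamics run
#'
#' @param s Selection strength, `>= 0`.
#' @param steps Number of strategy-revision time steps.
#' @param rounds_per_step Rounds played per block; default 20, as in the
#'   experimental sessions. Each block restarts from round 1 (initial
#'   contributions apply).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param aggregation `"sum"` or `"mean"` block utility.
#' @param strategy_mode `"reactive"` (full reactive-strategy space) or
#'   `"constant"` (memoryless strategies only; the no-reciprocity ablation).
#' @param burn_in Steps excluded from the aggregate totals (default 0: all
#'   rounds count, as used for fitting).
#' @param record `"none"` (aggregate totals only), `"steps"` (per-step block
#'   sums), or `"rounds"` (full round-level contributions; memory-guarded).
#' @param record_occupancy Count visits to each strategy profile (only for
#'   tiny strategy spaces; used to compare against the exact chain).
#' @return An `introspection_config` list.
#' @export
introspection_config <- function(s, steps, rounds_per_step = 20L, seed = NULL,
                                 aggregation = c("sum", "mean"),
                                 strategy_mode = c("reactive", "constant"),
                                 burn_in = 0L,
                                 record = c("none", "steps", "rounds"),
                                 record_occupancy = FALSE) {
  stopifnot(s >= 0, steps >= 1, rounds_per_step >= 1, burn_in >= 0,
            burn_in < steps)
  structure(list(s = s, steps = as.integer(steps),
                 rounds_per_step = as.integer(rounds_per_step), seed = seed,
                 aggregation = match.arg(aggregation),
                 strategy_mode = match.arg(strategy_mode),
                 burn_in = as.integer(burn_in), record = match.arg(record),
                 record_occupancy = record_occupancy),
            class = "introspection_config")
}

strategy_space_size <- function(spec, strategy_mode = "reactive") {
  e1 <- spec$e[1]; e2 <- spec$e[2]
  if (strategy_mode == "constant") c(e1 + 1, e2 + 1)
  else c((e1 + 1)^(e2 + 2), (e2 + 1)^(e1 + 2))
}

#' Run introspection dynamics
#'
#' Both strategies initialize uniformly at random. Each time step the
#' current pair plays a block of `rounds_per_step` rounds; one player,
#' chosen uniformly, draws a uniformly random alternative strategy, the
#' counterfactual block is re-rolled deterministically with the alternative
#' against the coplayer's unchanged strategy, and the player switches with
#' probability [switch_probability()]. Fully reproducible from the seed.
#'
#' @param spec A two-player `pgg_game`.
#' @param params A [utility_params()] object.
#' @param config An [introspection_config()].
#' @return A `pgg_sim` object: aggregate `totals` (summed contributions,
#'   payoffs, success and full-contribution round counts past burn-in),
#'   optional per-step matrix `steps`, optional round-level matrix `rounds`,
#'   optional `occupancy` counts, final strategies, and the inputs.
#' @examples
#' g <- make_treatment("linear", "FE")
#' sim <- run_introspection(g, utility_params(0, 14),
#'                          introspection_config(s = 1, steps = 2000, seed = 1))
#' group_overall_surplus(sim)
#' @export
run_introspection <- function(spec, params, config) {
  if (spec$n != 2) stop("run_introspection() supports two-player games only")
  stopifnot(inherits(params, "utility_params"),
            inherits(config, "introspection_config"))
  if (config$record == "rounds" &&
      as.double(config$steps) * config$rounds_per_step > 2e6)
    stop("record = 'rounds' is limited to steps * rounds_per_step <= 2e6")
  if (config$record_occupancy) {
    m <- prod(strategy_space_size(spec, config$strategy_mode))
    if (config$strategy_mode == "reactive" && m > 1e6)
      stop("occupancy recording needs a strategy-profile space <= 1e6, got ",
           format(m))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rw <- spec$reward
  is_thr <- rw$kind == "threshold"
  res <- introspection_run_cpp(
    spec$e[1], spec$e[2], spec$p_num, spec$p_den, is_thr,
    if (is_thr) rw$theta_num else 0, if (is_thr) rw$theta_den else 1,
    if (is_thr) rw$r else 0, params$beta, params$gamma, config$s,
    config$steps, config$rounds_per_step,
    config$aggregation == "mean", config$strategy_mode == "constant",
    config$record == "steps", config$record == "rounds",
    isTRUE(config$record_occupancy), config$burn_in)
  structure(c(res, list(game = spec, params = params, config = config)),
            class = "pgg_sim")
}

#' @export
print.pgg_sim <- function(x, ...) {
  tt <- x$totals
  cat(sprintf("Introspection dynamics: %d steps x %d rounds (%s)\n",
              x$config$steps, x$config$rounds_per_step,
              if (!is.null(x$game$label)) x$game$label else "custom game"))
  cat(sprintf("  s = %g, beta = %g, gamma = %g, mode = %s\n", x$config$s,
              x$params$beta, x$params$gamma, x$config$strategy_mode))
  cat(sprintf("  mean contributions: %.3f, %.3f of e = (%d, %d)\n",
              tt[["c1"]] / tt[["rounds"]], tt[["c2"]] / tt[["rounds"]],
              x$game$e[1], x$game$e[2]))
  cat(sprintf("  group overall surplus: %.4f\n",
              (tt[["pi1"]] + tt[["pi2"]] - tt[["rounds"]] * sum(x$game$e)) /
                (tt[["rounds"]] * sum(x$game$e))))
  invisible(x)
}

# Stationary distribution of a row-stochastic matrix by the
# Grassmann-Taksar-Heyman (GTH) state-reduction algorithm. GTH uses no
# subtractions, so it attains componentwise relative accuracy even when the
# chain is nearly reducible -- exactly the regime of strong selection, where
# switch probabilities like exp(-s * du) underflow any naive linear solve's
# conditioning. Diagonal entries (self-loops) are never referenced.
stationary_from_transition <- function(TM) {
  P <- TM
  n <- nrow(P)
  S <- numeric(n) # exit mass of state k at its elimination step
  for (k in n:2) {
    below <- seq_len(k - 1)
    S[k] <- sum(P[k, below])
    if (S[k] == 0)
      stop("switch probabilities underflow double precision at these ",
           "parameters (selection too strong); the stationary distribution ",
           "is not representable")
    P[k, below] <- P[k, below] / S[k]
    P[below, below] <- P[below, below] +
      outer(P[below, k], P[k, below])
  }
  v <- numeric(n)
  v[1] <- 1
  for (k in seq_len(n)[-1])
    v[k] <- sum(v[seq_len(k - 1)] * P[seq_len(k - 1), k]) / S[k]
  v / sum(v)
}

# Enumerate all strategies of one player as an m x (co_e + 2) integer matrix.
enumerate_strategies <- function(own_e, co_e, strategy_mode = "reactive") {
  if (strategy_mode == "constant") {
    vals <- 0:own_e
    return(matrix(rep(vals, co_e + 2), nrow = own_e + 1))
  }
  as.matrix(do.call(expand.grid, rep(list(0:own_e), co_e + 2)))
}

#' Exact stationary distribution of the introspection chain
#'
#' Builds the full transition matrix of the introspection-dynamics Markov
#' chain over strategy profiles of a tiny game and returns its unique
#' stationary distribution. The chain is ergodic for finite `s` (every
#' switch probability lies strictly between 0 and 1), so the distribution is
#' strictly positive and independent of initialization. Serves as the
#' independent oracle for the Monte Carlo simulator; all block utilities are
#' computed through the R-level [rollout()] / [block_utility()] path.
#'
#' @param spec A two-player `pgg_game` with a tiny strategy space (at most
#'   `10^4` strategy profiles).
#' @param params A [utility_params()] object.
#' @param s Selection strength.
#' @param aggregation `"sum"` or `"mean"` block utility.
#' @param rounds_per_step Rounds per block (default 20).
#' @param strategy_mode `"reactive"` or `"constant"`.
#' @return A list: `pi` (stationary probabilities, length `m1 * m2`, player
#'   2's strategy index varying fastest), `transition` (the transition
#'   matrix), `strategies1`, `strategies2` (the enumerated strategy tables).
#' @export
stationary_distribution_exact <- function(spec, params, s,
                                          aggregation = c("sum", "mean"),
                                          rounds_per_step = 20L,
                                          strategy_mode = c("reactive", "constant")) {
  aggregation <- match.arg(aggregation)
  strategy_mode <- match.arg(strategy_mode)
  if (spec$n != 2) stop("two-player games only")
  sz <- strategy_space_size(spec, strategy_mode)
  m1 <- sz[1]; m2 <- sz[2]
  if (m1 * m2 > 1e4)
    stop("strategy-profile space too large for exact analysis: ",
         format(m1 * m2), " > 1e4")
  S1 <- enumerate_strategies(spec$e[1], spec$e[2], strategy_mode)
  S2 <- enumerate_strategies(spec$e[2], spec$e[1], strategy_mode)

  U1 <- matrix(0, m1, m2)
  U2 <- matrix(0, m1, m2)
  for (i in seq_len(m1)) {
    R1 <- reactive_strategy(S1[i, 1], S1[i, -1], spec$e[1], spec$e[2])
    for (j in seq_len(m2)) {
      R2 <- reactive_strategy(S2[j, 1], S2[j, -1], spec$e[2], spec$e[1])
      u <- block_utility(spec, params,
                         rollout(spec, R1, R2, rounds_per_step), aggregation)
      U1[i, j] <- u[1]; U2[i, j] <- u[2]
    }
  }

  n_states <- m1 * m2
  idx <- function(i, j) (i - 1L) * m2 + j
  TM <- matrix(0, n_states, n_states)
  for (i in seq_len(m1)) for (j in seq_len(m2)) {
    st <- idx(i, j)
    # focal player 1 revises: move (i, j) -> (i2, j)
    phi1 <- switch_probability(U1[, j], U1[i, j], s)
    TM[st, idx(seq_len(m1), j)] <- TM[st, idx(seq_len(m1), j)] +
      0.5 * phi1 / m1
    # focal player 2 revises: move (i, j) -> (i, j2)
    phi2 <- switch_probability(U2[i, ], U2[i, j], s)
    TM[st, idx(i, seq_len(m2))] <- TM[st, idx(i, seq_len(m2))] +
      0.5 * phi2 / m2
    TM[st, st] <- TM[st, st] + 1 - sum(0.5 * phi1 / m1) - sum(0.5 * phi2 / m2)
  }

  pi_st <- stationary_from_transition(TM)
  list(pi = pi_st, transition = TM, strategies1 = S1, strategies2 = S2,
       utilities1 = U1, utilities2 = U2)
}
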