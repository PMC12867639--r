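# Game definitions and per-round payoffs.
#
# A public goods game: each round player i holds an integer endowment e_i and
# contributes c_i in {0, ..., e_i}. Contributions are scaled by individual
# productivity factors p_i; the collective contribution is C = sum(p_i * c_i).
# Payoffs are pi_i = (e_i - c_i) + r_i, where the reward r_i is C/n in the
# linear game, or a fixed r paid to everyone iff C >= theta in the threshold
# game.

#' Linear reward rule
#'
#' Each player's reward is an equal share `C/n` of the collective
#' contribution.
#'
#' @return A `pgg_reward` object of kind `"linear"`.
#' @seealso [reward_threshold()], [pgg_game()]
#' @export
reward_linear <- function() {
  structure(list(kind = "linear"), class = "pgg_reward")
}

#' Threshold (step) reward rule
#'
#' Every player receives the fixed reward `r` if and only if the collective
#' contribution reaches the threshold, `C >= theta`; otherwise no one
#' receives anything. The comparison is decided in exact rational arithmetic.
#'
#' @param theta Nonnegative threshold, in effective-contribution units.
#' @param r Positive reward paid to each player upon success.
#' @return A `pgg_reward` object of kind `"threshold"`.
#' @export
reward_threshold <- function(theta, r) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0,
            is.numeric(r), length(r) == 1, r > 0)
  th <- as_rational(theta)
  structure(list(kind = "threshold", theta = theta, r = r,
                 theta_num = th$num, theta_den = th$den),
            class = "pgg_reward")
}

#' Define a public goods game
#'
#' @param endowments Integer vector of per-player endowments, all `>= 1`.
#' @param productivities Numeric vector of per-player productivity factors,
#'   all `> 0`. Stored internally as exact rationals (e.g. `1.6` as `8/5`) so
#'   threshold crossing is decided exactly.
#' @param reward A reward rule from [reward_linear()] or [reward_threshold()].
#' @param label Optional treatment name.
#' @return A `pgg_game` object with fields `n`, `e`, `p`, `p_num`, `p_den`,
#'   `reward`, `label`.
#' @examples
#' g <- pgg_game(c(24, 24), c(1.6, 1.6))
#' payoffs(g, c(24, 24))
#' @export
pgg_game <- function(endowments, productivities, reward = reward_linear(),
                     label = NULL) {
  stopifnot(inherits(reward, "pgg_reward"))
  e <- as.integer(endowments)
  n <- length(e)
  if (n < 2) stop("a public goods game needs at least two players")
  if (length(productivities) != n)
    stop("endowments and productivities must have the same length")
  if (any(e < 1)) stop("all endowments must be >= 1")
  if (any(productivities <= 0)) stop("all productivities must be > 0")
  pr <- as_rational(productivities)
  structure(list(n = n, e = e, p = productivities,
                 p_num = pr$num, p_den = pr$den,
                 reward = reward, label = label),
            class = "pgg_game")
}

#' @export
print.pgg_game <- function(x, ...) {
  kind <- x$reward$kind
  cat(sprintf("Public goods game (%s)%s\n", kind,
              if (!is.null(x$label)) paste0(" -- ", x$label) else ""))
  cat(sprintf("  n = %d players\n", x$n))
  cat("  endowments:     ", paste(x$e, collapse = ", "), "\n")
  cat("  productivities: ", paste(format(x$p), collapse = ", "), "\n")
  if (kind == "threshold")
    cat(sprintf("  threshold = %s, reward = %s\n",
                format(x$reward$theta), format(x$reward$r)))
  invisible(x)
}

#' Validate a contribution profile
#'
#' @param spec A `pgg_game`.
#' @param profile Integer vector of contributions, one per player.
#' @return The profile, invisibly, as integer; errors if invalid.
#' @keywords internal
check_profile <- function(spec, profile) {
  if (length(profile) != spec$n)
    stop("profile length ", length(profile), " does not match n = ", spec$n)
  if (any(profile != round(profile)))
    stop("contributions must be integers")
  c_i <- as.integer(round(profile))
  if (any(c_i < 0) || any(c_i > spec$e))
    stop("contributions must satisfy 0 <= c_i <= e_i")
  invisible(c_i)
}

#' Collective contribution
#'
#' Computes `C = sum(p_i * c_i)`, the group's collective contribution.
#'
#' @inheritParams check_profile
#' @return A single number.
#' @export
collective_contribution <- function(spec, profile) {
  c_i <- check_profile(spec, profile)
  sum(spec$p_num * c_i) / spec$p_den
}

# Exact threshold indicator: C >= theta as an integer comparison.
threshold_met <- function(spec, c_i) {
  rw <- spec$reward
  # sum(p_num*c)/p_den >= theta_num/theta_den, all terms exact in doubles
  sum(spec$p_num * c_i) * rw$theta_den >= rw$theta_num * spec$p_den
}

#' Per-round payoffs
#'
#' `pi_i = (e_i - c_i) + r_i`, with `r_i = C/n` in the linear game and
#' `r_i = r * [C >= theta]` in the threshold game (weak inequality, decided
#' exactly).
#'
#' @inheritParams check_profile
#' @return Numeric vector of payoffs, one per player.
#' @export
payoffs <- function(spec, profile) {
  c_i <- check_profile(spec, profile)
  kept <- spec$e - c_i
  if (spec$reward$kind == "linear") {
    kept + sum(spec$p_num * c_i) / spec$p_den / spec$n
  } else {
    kept + if (threshold_met(spec, c_i)) spec$reward$r else 0
  }
}

#' Social dilemma test for linear games
#'
#' A linear public goods game is a social dilemma when `1 < p_i < n` for
#' every player: the group gains from every contribution, yet each unit
#' contributed returns only `p_i/n < 1` to the contributor.
#'
#' @param spec A `pgg_game` with a linear reward rule.
#' @return `TRUE` or `FALSE`.
#' @export
is_social_dilemma <- function(spec) {
  if (spec$reward$kind != "linear")
    stop("is_social_dilemma() is defined for linear games only")
  all(spec$p > 1 & spec$p < spec$n)
}
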