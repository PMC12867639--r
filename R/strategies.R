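# Deterministic reactive strategies for repeated two-player games.
#
# A reactive strategy is an initial contribution plus a full response table:
# entry j of the table is the owner's next contribution after seeing the
# coplayer contribute j in the previous round. Two such strategies uniquely
# determine play for any number of rounds.

#' Construct a reactive strategy
#'
#' @param initial Integer contribution for round 1, in `0:owner_e`.
#' @param response Integer vector of length `coplayer_e + 1`; entry `j + 1`
#'   is the owner's contribution after the coplayer contributed `j`.
#' @param owner_e Owner's endowment.
#' @param coplayer_e Coplayer's endowment.
#' @return A `reactive_strategy` object.
#' @export
reactive_strategy <- function(initial, response, owner_e, coplayer_e) {
  initial <- as.integer(initial)
  response <- as.integer(response)
  if (length(response) != coplayer_e + 1)
    stop("response table must have length coplayer_e + 1 = ", coplayer_e + 1)
  if (initial < 0 || initial > owner_e)
    stop("initial contribution out of range 0..", owner_e)
  if (any(response < 0) || any(response > owner_e))
    stop("response entries out of range 0..", owner_e)
  structure(list(initial = initial, response = response,
                 owner_e = as.integer(owner_e),
                 coplayer_e = as.integer(coplayer_e)),
            class = "reactive_strategy")
}

#' @export
print.reactive_strategy <- function(x, ...) {
  cat(sprintf("Reactive strategy (endowment %d vs coplayer %d)\n",
              x$owner_e, x$coplayer_e))
  cat("  initial:", x$initial, "\n")
  cat("  response to 0..", x$coplayer_e, ": ",
      paste(x$response, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Draw a uniformly random reactive strategy
#'
#' Every entry (initial plus all `coplayer_e + 1` responses) is drawn
#' independently and uniformly from `0:owner_e` — i.e. the strategy is
#' uniform over the full reactive-strategy space. Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams reactive_strategy
#' @return A `reactive_strategy`.
#' @export
random_strategy <- function(owner_e, coplayer_e) {
  draws <- sample.int(owner_e + 1L, coplayer_e + 2L, replace = TRUE) - 1L
  reactive_strategy(draws[1], draws[-1], owner_e, coplayer_e)
}

#' Constant (memoryless) strategy
#'
#' Contributes `c` in every round regardless of the coplayer. Used for the
#' no-reciprocity ablation of the learning model.
#'
#' @param c Integer contribution in `0:owner_e`.
#' @inheritParams reactive_strategy
#' @return A `reactive_strategy` whose initial and all responses equal `c`.
#' @export
constant_strategy <- function(c, owner_e, coplayer_e) {
  reactive_strategy(c, rep(c, coplayer_e + 1), owner_e, coplayer_e)
}

#' Roll out deterministic repeated play
#'
#' Round 1 uses both players' initial contributions; in round `t > 1` each
#' player plays their response to the coplayer's round `t - 1` contribution.
#'
#' @param spec A two-player `pgg_game`.
#' @param R1,R2 `reactive_strategy` objects for players 1 and 2, dimensioned
#'   for `spec`'s endowments.
#' @param rounds Number of rounds, `>= 1`.
#' @return A `pgg_trace`: list with integer matrix `contributions`
#'   (rounds x 2) and numeric matrix `payoffs` (rounds x 2), plus the game.
#' @examples
#' g <- make_treatment("linear", "FE")
#' tft <- reactive_strategy(24, 0:24, 24, 24)  # match coplayer's last move
#' rollout(g, tft, tft, 20)
#' @export
rollout <- function(spec, R1, R2, rounds) {
  if (spec$n != 2) stop("rollout() supports two-player games only")
  stopifnot(inherits(R1, "reactive_strategy"), inherits(R2, "reactive_strategy"),
            rounds >= 1)
  if (R1$owner_e != spec$e[1] || R1$coplayer_e != spec$e[2])
    stop("R1 is dimensioned for endowments (", R1$owner_e, ", ", R1$coplayer_e,
         "), game has (", spec$e[1], ", ", spec$e[2], ")")
  if (R2$owner_e != spec$e[2] || R2$coplayer_e != spec$e[1])
    stop("R2 is dimensioned for endowments (", R2$owner_e, ", ", R2$coplayer_e,
         "), game has (", spec$e[2], ", ", spec$e[1], ")")
  cc <- matrix(0L, rounds, 2)
  cc[1, ] <- c(R1$initial, R2$initial)
  if (rounds > 1)
    for (t in 2:rounds) {
      cc[t, 1] <- R1$response[cc[t - 1, 2] + 1L]
      cc[t, 2] <- R2$response[cc[t - 1, 1] + 1L]
    }
  pp <- t(apply(cc, 1, function(row) payoffs(spec, row)))
  structure(list(contributions = cc, payoffs = pp, game = spec),
            class = "pgg_trace")
}

#' @export
print.pgg_trace <- function(x, ...) {
  cat(sprintf("Play trace: %d rounds of %s\n", nrow(x$contributions),
              if (!is.null(x$game$label)) x$game$label else "a public goods game"))
  show_n <- min(6, nrow(x$contributions))
  df <- data.frame(round = seq_len(show_n),
                   x$contributions[seq_len(show_n), , drop = FALSE],
                   round(x$payoffs[seq_len(show_n), , drop = FALSE], 3))
  names(df) <- c("round", paste0("c", 1:2), paste0("pi", 1:2))
  print(df, row.names = FALSE)
  if (nrow(x$contributions) > show_n) cat("  ...\n")
  invisible(x)
}

#' Convert a play trace to round records
#'
#' @param trace A `pgg_trace`.
#' @param group_id,session,game_type,treatment Identifiers for the records.
#' @return A data frame in the canonical round-record schema (see
#'   [read_rounds()]).
#' @export
as_round_records <- function(trace, group_id = 1L, session = 1L,
                             game_type = NULL, treatment = NULL) {
  spec <- trace$game
  rounds <- nrow(trace$contributions)
  if (is.null(game_type)) game_type <- spec$reward$kind
  if (is.null(treatment)) treatment <- if (!is.null(spec$label)) spec$label else "custom"
  do.call(rbind, lapply(seq_len(spec$n), function(i) {
    data.frame(game_type = game_type, treatment = treatment,
               group_id = group_id, session = session,
               round = seq_len(rounds), role = i,
               contribution = trace$contributions[, i],
               endowment = spec$e[i], productivity = spec$p[i],
               payoff = trace$payoffs[, i])
  }))
}
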