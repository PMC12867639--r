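# Canonical round-level data schema, CSV readers/writers, and a synthetic
# behavioral-data generator.
#
# One row per player per round:
#   game_type, treatment, group_id, session, round, role, contribution,
#   endowment, productivity, payoff

ROUND_COLUMNS <- c("game_type", "treatment", "group_id", "session", "round",
                   "role", "contribution", "endowment", "productivity",
                   "payoff")

#' Write round records to CSV
#'
#' @param records Data frame in the canonical round-record schema.
#' @param path Output path (UTF-8, header row, comma-separated).
#' @export
write_rounds <- function(records, path) {
  missing_cols <- setdiff(ROUND_COLUMNS, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[, ROUND_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate round records
#'
#' Validates the canonical schema row by row and reports all violations with
#' their CSV line numbers (header = line 1).
#'
#' @param path CSV path.
#' @param check_payoffs Recompute payoffs from the assembled per-round
#'   contribution profiles and compare (linear games, or threshold games
#'   when `spec` is given).
#' @param spec Optional `pgg_game` supplying the reward rule for the payoff
#'   check of threshold data.
#' @return A validated data frame of round records.
#' @export
read_rounds <- function(path, check_payoffs = FALSE, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(ROUND_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L
  problems <- character(0)
  bad <- function(mask, msg) {
    if (any(mask))
      problems <<- c(problems, paste0("line ", line[mask], ": ", msg))
  }
  bad(!df$game_type %in% c("linear", "threshold"),
      "game_type must be 'linear' or 'threshold'")
  bad(df$round < 1 | df$round != round(df$round), "round must be an integer >= 1")
  bad(df$role < 1 | df$role != round(df$role), "role must be an integer >= 1")
  bad(df$endowment < 1, "endowment must be >= 1")
  bad(df$productivity <= 0, "productivity must be > 0")
  bad(df$contribution < 0 | df$contribution > df$endowment |
        df$contribution != round(df$contribution),
      "contribution must be an integer in 0..endowment")
  if (length(problems))
    stop("invalid round records:\n", paste(utils::head(problems, 20),
                                           collapse = "\n"))
  if (check_payoffs) {
    for (g in records_by_group(df)) {
      gspec <- if (!is.null(spec)) spec
      else pgg_game(g$e, g$p, reward_linear())
      for (t in seq_len(nrow(g$contributions))) {
        expect <- payoffs(gspec, g$contributions[t, ])
        if (any(abs(expect - g$payoffs[t, ]) > 1e-6))
          stop("payoff inconsistency in round ", t,
               ": recorded (", paste(round(g$payoffs[t, ], 4), collapse = ", "),
               "), recomputed (", paste(round(expect, 4), collapse = ", "), ")")
      }
    }
  }
  df
}

#' Generate synthetic round-level behavioral data
#'
#' A deliberately simple generative fixture, not a behavioral model: each
#' player mixes a fairness target with in-kind reciprocation of the
#' coplayer's last contribution (rescaled to their own endowment) plus
#' Gaussian noise, rounded and clamped to the action set. Round 1 starts
#' from the fairness target. It emulates the two structures observed in
#' pairwise play: positive lag-1 reciprocity in linear games, and
#' coordination near half-endowment contributions in threshold games.
#'
#' @param spec A two-player `pgg_game`.
#' @param groups Number of independent groups.
#' @param rounds Rounds per group (default 20).
#' @param seed Integer seed.
#' @param reciprocity Weight in `[0, 1]` on the coplayer's last (rescaled)
#'   contribution; `0` = pure fairness target, `1` = pure in-kind matching.
#' @param target Fairness target: `"half_endowment"` (`e_i/2`),
#'   `"equal_relative"` (`level * e_i`), or `"equal_absolute"`
#'   (`level * min(e)` for both players).
#' @param level Target level as a fraction (default 0.5).
#' @param noise_sd Standard deviation of the Gaussian contribution noise, in
#'   endowment units.
#' @param session Session identifier for the records.
#' @return A data frame of round records (2 rows per round per group).
#' @export
synth_behavior <- function(spec, groups, rounds = 20L, seed = NULL,
                           reciprocity = 0.5,
                           target = c("half_endowment", "equal_relative",
                                      "equal_absolute"),
                           level = 0.5, noise_sd = 1, session = 1L) {
  if (spec$n != 2) stop("synth_behavior() supports two-player games only")
  target <- match.arg(target)
  stopifnot(reciprocity >= 0, reciprocity <= 1, noise_sd >= 0,
            level >= 0, level <= 1)
  if (!is.null(seed)) set.seed(seed)
  e <- spec$e
  t_i <- switch(target,
                half_endowment = e / 2,
                equal_relative = level * e,
                equal_absolute = rep(level * min(e), 2))
  out <- vector("list", groups)
  for (gid in seq_len(groups)) {
    cc <- matrix(0L, rounds, 2)
    cc[1, ] <- pmin(pmax(round(t_i + stats::rnorm(2, 0, noise_sd)), 0), e)
    if (rounds > 1)
      for (t in 2:rounds) {
        matched <- rev(cc[t - 1, ]) * e / rev(e) # coplayer's c scaled to own e
        raw <- (1 - reciprocity) * t_i + reciprocity * matched +
          stats::rnorm(2, 0, noise_sd)
        cc[t, ] <- pmin(pmax(round(raw), 0), e)
      }
    pp <- t(apply(cc, 1, function(row) payoffs(spec, row)))
    trace <- structure(list(contributions = cc, payoffs = pp, game = spec),
                       class = "pgg_trace")
    out[[gid]] <- as_round_records(trace, group_id = gid, session = session)
  }
  do.call(rbind, out)
}
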