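# Outcome statistics: the variables reported for behavioral public goods
# experiments, computable from a deterministic play trace, a simulation run,
# or round-level records. For round-record data frames, statistics are
# averaged over rounds within each group/session first, then across groups.

trace_spec <- function(x, spec) {
  if (is.null(spec)) {
    if (!is.null(x[["game"]])) return(x[["game"]])
    stop("spec must be supplied for this input")
  }
  spec
}

# Split round records into per-group contribution/payoff matrices.
records_by_group <- function(df) {
  key <- interaction(df$group_id, df$session, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$round, d$role), ]
    roles <- sort(unique(d$role))
    rounds <- sort(unique(d$round))
    cc <- matrix(d$contribution[order(d$role, d$round)],
                 nrow = length(rounds), ncol = length(roles))
    pp <- matrix(d$payoff[order(d$role, d$round)],
                 nrow = length(rounds), ncol = length(roles))
    e <- vapply(roles, function(r) d$endowment[d$role == r][1], numeric(1))
    p <- vapply(roles, function(r) d$productivity[d$role == r][1], numeric(1))
    list(contributions = cc, payoffs = pp, e = e, p = p)
  })
}

# Average a per-group statistic across groups.
group_mean <- function(df, f) {
  vals <- vapply(records_by_group(df), f, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Group relative contribution
#'
#' Mean over rounds of `sum(c_i) / sum(e_i)`, the fraction of the total
#' endowment the group contributes.
#'
#' @param x A `pgg_trace`, `pgg_sim`, or round-record data frame.
#' @param spec The `pgg_game` (taken from `x` when available).
#' @return A fraction in `[0, 1]`.
#' @export
group_relative_contribution <- function(x, spec = NULL) {
  UseMethod("group_relative_contribution")
}

#' @export
group_relative_contribution.pgg_trace <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  mean(rowSums(x$contributions)) / sum(spec$e)
}

#' @export
group_relative_contribution.pgg_sim <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  tt <- x$totals
  (tt[["c1"]] + tt[["c2"]]) / (tt[["rounds"]] * sum(spec$e))
}

#' @export
group_relative_contribution.data.frame <- function(x, spec = NULL) {
  group_mean(x, function(g) mean(rowSums(g$contributions)) / sum(g$e))
}

#' Group overall surplus (GOS)
#'
#' Mean over rounds of `(sum(pi_i) - sum(e_i)) / sum(e_i)`: the group's
#' relative payoff gain over its endowments. Zero under full defection in
#' both game types.
#'
#' @inheritParams group_relative_contribution
#' @return A number (a fraction of the total endowment).
#' @export
group_overall_surplus <- function(x, spec = NULL) {
  UseMethod("group_overall_surplus")
}

#' @export
group_overall_surplus.pgg_trace <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  (mean(rowSums(x$payoffs)) - sum(spec$e)) / sum(spec$e)
}

#' @export
group_overall_surplus.pgg_sim <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  tt <- x$totals
  (tt[["pi1"]] + tt[["pi2"]] - tt[["rounds"]] * sum(spec$e)) /
    (tt[["rounds"]] * sum(spec$e))
}

#' @export
group_overall_surplus.data.frame <- function(x, spec = NULL) {
  group_mean(x, function(g) (mean(rowSums(g$payoffs)) - sum(g$e)) / sum(g$e))
}

#' Success rate of a threshold game
#'
#' Fraction of rounds in which the collective contribution reaches the
#' threshold (`C >= theta`). Defined for threshold games only.
#'
#' @inheritParams group_relative_contribution
#' @return A fraction in `[0, 1]`.
#' @export
success_rate <- function(x, spec = NULL) UseMethod("success_rate")

check_threshold_spec <- function(spec) {
  if (spec$reward$kind != "threshold")
    stop("success_rate() is defined for threshold games only")
  spec
}

#' @export
success_rate.pgg_trace <- function(x, spec = NULL) {
  spec <- check_threshold_spec(trace_spec(x, spec))
  mean(apply(x$contributions, 1, function(row) threshold_met(spec, row)))
}

#' @export
success_rate.pgg_sim <- function(x, spec = NULL) {
  spec <- check_threshold_spec(trace_spec(x, spec))
  x$totals[["success"]] / x$totals[["rounds"]]
}

#' @export
success_rate.data.frame <- function(x, spec = NULL) {
  if (!is.null(spec)) {
    spec <- check_threshold_spec(spec)
    return(group_mean(x, function(g)
      mean(apply(g$contributions, 1, function(row) threshold_met(spec, row)))))
  }
  # without a game spec, infer success from the records themselves: in a
  # threshold game a round succeeded iff the reward was paid, i.e. the
  # payoff exceeds the kept endowment
  if (!all(x$game_type == "threshold"))
    stop("success_rate() is defined for threshold games only")
  group_mean(x, function(g) {
    kept <- sweep(-g$contributions, 2, g$e, "+")
    mean(rowSums(g$payoffs - kept) > 1e-9)
  })
}

#' Gini coefficient
#'
#' Population (pairwise mean-difference) form,
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))`, without small-sample correction.
#' Scale-invariant; 0 for perfect equality; at most `(n - 1) / n`.
#'
#' @param values Nonnegative numbers (endowments or payoffs), at least one
#'   strictly positive.
#' @return A fraction in `[0, 1)`.
#' @examples
#' gini(c(36, 12))  # 0.25
#' @export
gini <- function(values) {
  stopifnot(all(values >= 0))
  if (all(values == 0)) stop("Gini coefficient is undefined for all-zero input")
  n <- length(values)
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * mean(values))
}

#' Per-role mean absolute and relative contributions
#'
#' @inheritParams group_relative_contribution
#' @return A data frame with one row per role: `role`, `endowment`,
#'   `mean_contribution`, `mean_relative_contribution`.
#' @export
role_contributions <- function(x, spec = NULL) UseMethod("role_contributions")

#' @export
role_contributions.pgg_trace <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  mc <- colMeans(x$contributions)
  data.frame(role = seq_len(spec$n), endowment = spec$e,
             mean_contribution = mc, mean_relative_contribution = mc / spec$e)
}

#' @export
role_contributions.pgg_sim <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  tt <- x$totals
  mc <- c(tt[["c1"]], tt[["c2"]]) / tt[["rounds"]]
  data.frame(role = 1:2, endowment = spec$e,
             mean_contribution = mc, mean_relative_contribution = mc / spec$e)
}

#' @export
role_contributions.data.frame <- function(x, spec = NULL) {
  groups <- records_by_group(x)
  roles <- seq_along(groups[[1]]$e)
  mc <- rowMeans(vapply(groups, function(g) colMeans(g$contributions),
                        numeric(length(roles))))
  rel <- rowMeans(vapply(groups, function(g)
    colMeans(g$contributions) / g$e, numeric(length(roles))))
  data.frame(role = roles, endowment = groups[[1]]$e,
             mean_contribution = mc, mean_relative_contribution = rel)
}

#' Fraction of rounds with full contribution
#'
#' The proportion of rounds in which every player contributes their entire
#' endowment.
#'
#' @inheritParams group_relative_contribution
#' @return A fraction in `[0, 1]`.
#' @export
full_contribution_fraction <- function(x, spec = NULL) {
  UseMethod("full_contribution_fraction")
}

#' @export
full_contribution_fraction.pgg_trace <- function(x, spec = NULL) {
  spec <- trace_spec(x, spec)
  mean(apply(x$contributions, 1, function(row) all(row == spec$e)))
}

#' @export
full_contribution_fraction.pgg_sim <- function(x, spec = NULL) {
  x$totals[["full"]] / x$totals[["rounds"]]
}

#' @export
full_contribution_fraction.data.frame <- function(x, spec = NULL) {
  group_mean(x, function(g)
    mean(apply(g$contributions, 1, function(row) all(row == g$e))))
}

# Pearson correlation, NA (undefined) for constant series instead of error.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Lag-1 reciprocity correlation
#'
#' Per player, the Pearson correlation between their contribution in round
#' `t` and the coplayer's contribution in round `t - 1`. Strongly positive
#' under reciprocal (in-kind) play; weak or negative in coordination play.
#' Constant series make the correlation undefined and return `NA`.
#'
#' @inheritParams group_relative_contribution
#' @return Numeric vector `c(player1, player2)`; for data frames, the
#'   across-group mean of the per-group correlations (`NA`s dropped).
#' @export
reciprocity_lag_correlation <- function(x, spec = NULL) {
  UseMethod("reciprocity_lag_correlation")
}

lag_cor_matrix <- function(cc) {
  T_ <- nrow(cc)
  if (T_ < 3) stop("need at least 3 rounds for a lag-1 correlation")
  c(safe_cor(cc[2:T_, 1], cc[1:(T_ - 1), 2]),
    safe_cor(cc[2:T_, 2], cc[1:(T_ - 1), 1]))
}

#' @export
reciprocity_lag_correlation.pgg_trace <- function(x, spec = NULL) {
  lag_cor_matrix(x$contributions)
}

#' @export
reciprocity_lag_correlation.data.frame <- function(x, spec = NULL) {
  per_group <- vapply(records_by_group(x), function(g)
    lag_cor_matrix(g$contributions), numeric(2))
  rowMeans(per_group, na.rm = TRUE)
}

#' Early-versus-late contribution trend
#'
#' Mean group relative contribution over the first `k` and the last `k`
#' rounds, for trend comparisons.
#'
#' @param x A `pgg_trace` or round-record data frame.
#' @param spec The `pgg_game` (taken from `x` when available).
#' @param k Number of rounds in each window (default 5).
#' @return Named vector `c(first = ..., last = ...)`.
#' @export
trend_first_last <- function(x, spec = NULL, k = 5) {
  UseMethod("trend_first_last")
}

#' @export
trend_first_last.pgg_trace <- function(x, spec = NULL, k = 5) {
  spec <- trace_spec(x, spec)
  T_ <- nrow(x$contributions)
  if (T_ < 2 * k) stop("need at least 2k = ", 2 * k, " rounds")
  grc <- rowSums(x$contributions) / sum(spec$e)
  c(first = mean(grc[1:k]), last = mean(grc[(T_ - k + 1):T_]))
}

#' @export
trend_first_last.data.frame <- function(x, spec = NULL, k = 5) {
  per_group <- vapply(records_by_group(x), function(g) {
    T_ <- nrow(g$contributions)
    if (T_ < 2 * k) stop("need at least 2k = ", 2 * k, " rounds")
    grc <- rowSums(g$contributions) / sum(g$e)
    c(mean(grc[1:k]), mean(grc[(T_ - k + 1):T_]))
  }, numeric(2))
  c(first = mean(per_group[1, ]), last = mean(per_group[2, ]))
}

#' All outcome variables at once
#'
#' @inheritParams group_relative_contribution
#' @return A `pgg_summary` list: group relative contribution, group overall
#'   surplus, success rate (threshold games; `NA` otherwise), Gini
#'   coefficients of endowments and of mean payoffs, per-role contributions,
#'   and the full-contribution round fraction.
#' @export
group_summary <- function(x, spec = NULL) {
  spec_known <- tryCatch(trace_spec(x, spec), error = function(e) NULL)
  is_thr <- if (!is.null(spec_known)) spec_known$reward$kind == "threshold"
            else "threshold" %in% unique(x$game_type)
  roles <- role_contributions(x, spec)
  mean_pay <- if (inherits(x, "pgg_trace")) {
    colMeans(x$payoffs)
  } else if (inherits(x, "pgg_sim")) {
    c(x$totals[["pi1"]], x$totals[["pi2"]]) / x$totals[["rounds"]]
  } else {
    groups <- records_by_group(x)
    rowMeans(vapply(groups, function(g) colMeans(g$payoffs),
                    numeric(length(groups[[1]]$e))))
  }
  e <- if (!is.null(spec_known)) spec_known$e else records_by_group(x)[[1]]$e
  structure(list(
    group_relative_contribution = group_relative_contribution(x, spec),
    group_overall_surplus = group_overall_surplus(x, spec),
    success_rate = if (is_thr) success_rate(x, spec) else NA_real_,
    gini_endowments = gini(e),
    gini_payoffs = gini(mean_pay),
    role_contributions = roles,
    full_contribution_fraction = full_contribution_fraction(x, spec)),
    class = "pgg_summary")
}

#' @export
print.pgg_summary <- function(x, ...) {
  cat("Group summary\n")
  cat(sprintf("  relative contribution:      %.4f\n",
              x$group_relative_contribution))
  cat(sprintf("  overall surplus (GOS):      %.4f\n", x$group_overall_surplus))
  if (!is.na(x$success_rate))
    cat(sprintf("  success rate:               %.4f\n", x$success_rate))
  cat(sprintf("  Gini endowments -> payoffs: %.4f -> %.4f\n",
              x$gini_endowments, x$gini_payoffs))
  cat(sprintf("  full-contribution rounds:   %.4f\n",
              x$full_contribution_fraction))
  cat("  per-role contributions:\n")
  print(x$role_contributions, row.names = FALSE, digits = 4)
  invisible(x)
}
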