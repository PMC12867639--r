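# Treatment factory backed by a versioned YAML registry.
#
# The five two-player scenarios: FE (full equality), EI (endowment
# inequality), PI (productivity inequality), AI (aligned inequality: the more
# productive player holds the larger endowment), MI (misaligned inequality).
# Endowments are normalized to sum(e) = 48 per pair of roles; the average
# productivity is 1.6; thresholds default to theta = sum(p_i e_i)/2 with
# reward r = 20, so the threshold is guaranteed to be reached when every
# player contributes at least half their endowment.

SCENARIOS <- c("FE", "EI", "PI", "AI", "MI")

#' Load the treatment registry
#'
#' @param path Path to a registry YAML file; defaults to the one shipped with
#'   the package.
#' @return A list of treatment entries.
#' @export
treatment_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "treatments.yaml", package = "asympgg")
  yaml::read_yaml(path)$treatments
}

#' Build a treatment game from the registry
#'
#' Looks up the endowments, productivities, and (for threshold games) the
#' threshold and reward in the registry, applies any overrides, and returns a
#' [pgg_game()]. Parameters the registry does not carry (placeholder value
#' `"FIG1"`, or a missing entry) must be supplied via `overrides`; the
#' factory never invents them.
#'
#' @param game_type `"linear"` or `"threshold"`.
#' @param scenario One of `"FE"`, `"EI"`, `"PI"`, `"AI"`, `"MI"`.
#' @param n Group size, 2 or 4. For `n = 4` only FE/AI/MI exist.
#' @param overrides Named list; any of `e`, `p`, `theta`, `r`. When `e` or
#'   `p` is overridden and `theta` is not, the threshold is recomputed by its
#'   defining rule `theta = sum(p * e) / 2`.
#' @param registry Optional registry list from [treatment_registry()].
#' @return A `pgg_game` labelled `"<game_type>:<scenario>:n<n>"`.
#' @examples
#' make_treatment("linear", "FE")
#' make_treatment("threshold", "FE", overrides = list(p = c(1, 1)))  # theta = 24
#' @export
make_treatment <- function(game_type = c("linear", "threshold"),
                           scenario, n = 2, overrides = list(),
                           registry = NULL) {
  game_type <- match.arg(game_type)
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(n %in% c(2L, 4L))
  if (is.null(registry)) registry <- treatment_registry()

  hit <- Filter(function(t) t$game_type == game_type &&
                  t$scenario == scenario && t$n_players == n, registry)
  if (length(hit) == 0)
    stop(sprintf("unspecified-parameter: no registry entry for %s:%s with n=%d; ",
                 game_type, scenario, n),
         "supply e and p (and theta, r for threshold games) via overrides")
  entry <- hit[[1]]

  take <- function(name) {
    v <- if (!is.null(overrides[[name]])) overrides[[name]] else entry[[name]]
    if (is.null(v) || identical(v, "FIG1") || any(v == "FIG1"))
      stop(sprintf("unspecified-parameter: '%s' for %s:%s (n=%d) is not in the registry; ",
                   name, game_type, scenario, n),
           "supply it via overrides or a registry file")
    v
  }

  e <- as.numeric(take("e"))
  p <- as.numeric(take("p"))
  label <- sprintf("%s:%s:n%d", game_type, scenario, n)
  if (game_type == "linear")
    return(pgg_game(e, p, reward_linear(), label = label))

  theta <- if (!is.null(overrides$theta)) {
    overrides$theta
  } else if (!is.null(overrides$e) || !is.null(overrides$p)) {
    sum(p * e) / 2
  } else {
    as.numeric(take("theta"))
  }
  r <- if (!is.null(overrides$r)) overrides$r else {
    v <- entry$r
    if (is.null(v)) 20 else as.numeric(v)
  }
  pgg_game(e, p, reward_threshold(theta, r), label = label)
}

#' Parse a treatment label like "linear:AI" or "threshold:FE:n4"
#'
#' @param label Character, `"<game_type>:<scenario>"` with optional `":n<k>"`.
#' @param ... Passed to [make_treatment()].
#' @return A `pgg_game`.
#' @export
parse_treatment <- function(label, ...) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("treatment label must look like 'linear:FE'")
  n <- if (length(parts) >= 3) as.integer(sub("^n", "", parts[[3]])) else 2L
  make_treatment(parts[[1]], parts[[2]], n = n, ...)
}
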