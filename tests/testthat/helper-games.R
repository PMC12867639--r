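# Shared fixtures and independent oracles.

# Independent brute-force Nash check: plain double loop over profiles and
# unilateral deviations, no shared code with enumerate_pure_nash().
brute_force_nash <- function(spec) {
  grids <- lapply(spec$e, function(ei) 0:ei)
  profiles <- as.matrix(do.call(expand.grid, grids))
  is_nash <- logical(nrow(profiles))
  for (k in seq_len(nrow(profiles))) {
    prof <- profiles[k, ]
    base <- payoffs(spec, prof)
    ok <- TRUE
    for (i in seq_len(spec$n)) {
      for (ci in 0:spec$e[i]) {
        if (ci == prof[i]) next
        dev <- prof
        dev[i] <- ci
        if (payoffs(spec, dev)[i] > base[i] + 1e-9) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    is_nash[k] <- ok
  }
  m <- profiles[is_nash, , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Canonical ordering so Nash sets can be compared as sets.
profile_key <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(apply(m, 1, paste, collapse = ","))
}

random_small_game <- function(kind = c("linear", "threshold"), max_e = 6) {
  kind <- match.arg(kind)
  e <- sample(1:max_e, 2, replace = TRUE)
  p <- sample(c(0.8, 1.2, 1.3, 1.6, 1.9, 2.5), 2, replace = TRUE)
  if (kind == "linear") return(pgg_game(e, p, reward_linear()))
  theta <- round(stats::runif(1, 0.5, sum(p * e)), 1)
  pgg_game(e, p, reward_threshold(theta, r = sample(2:20, 1)))
}

tiny_game <- function(beta = 0, gamma = 0) {
  pgg_game(c(1, 1), c(1.6, 1.6), label = "tiny")
}

tit_for_tat <- function(spec, player = 1) {
  own <- spec$e[player]
  co <- spec$e[3 - player]
  # contribute the same fraction of own endowment the coplayer just gave
  resp <- as.integer(round((0:co) / co * own))
  reactive_strategy(own, resp, own, co)
}
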