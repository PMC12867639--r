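test_that("collective contribution and payoffs match hand arithmetic", {
  fe <- make_treatment("linear", "FE")
  expect_equal(collective_contribution(fe, c(24, 24)), 76.8)
  expect_equal(payoffs(fe, c(24, 24)), c(38.4, 38.4))
  expect_equal(payoffs(fe, c(0, 0)), c(24, 24))

  ei <- make_treatment("linear", "EI")
  expect_equal(collective_contribution(ei, c(36, 12)), 76.8)
  expect_equal(collective_contribution(ei, c(0, 0)), 0)

  toy <- pgg_game(c(24, 24), c(1, 1), reward_threshold(theta = 24, r = 20))
  expect_equal(payoffs(toy, c(12, 12)), c(32, 32)) # C = 24 >= theta
  expect_equal(payoffs(toy, c(12, 11)), c(12, 13)) # C = 23 < theta
})

test_that("contribution profiles are validated", {
  g <- make_treatment("linear", "EI")
  expect_error(payoffs(g, c(37, 0)), "0 <= c_i <= e_i")
  expect_error(payoffs(g, c(-1, 0)), "0 <= c_i <= e_i")
  expect_error(payoffs(g, c(1.5, 0)), "integer")
  expect_error(collective_contribution(g, c(0, 0, 0)), "does not match")
})

test_that("payoff conservation holds exactly on random profiles", {
  set.seed(11)
  lin <- make_treatment("linear", "AI")
  thr <- make_treatment("threshold", "AI")
  for (k in 1:200) {
    c_i <- c(sample(0:36, 1), sample(0:12, 1))
    # linear: sum(pi) = sum(e) + sum((p - 1) c); both sides share one
    # floating representation of p, so equality is exact
    pl <- payoffs(lin, c_i)
    expect_equal(sum(pl), sum(lin$e) + sum((lin$p_num / lin$p_den - 1) * c_i))
    # threshold: sum(pi) = sum(e) - sum(c) + n r [C >= theta]
    pt <- payoffs(thr, c_i)
    met <- collective_contribution(thr, c_i) >= thr$reward$theta
    expect_equal(sum(pt), sum(thr$e) - sum(c_i) + 2 * 20 * met)
  }
})

test_that("linear-game monotonicity: others gain p_j/n per unit, self p_j/n - 1", {
  g <- make_treatment("linear", "AI")
  base <- payoffs(g, c(10, 5))
  up <- payoffs(g, c(11, 5))
  expect_equal(up[2] - base[2], g$p[1] / 2)
  expect_equal(up[1] - base[1], g$p[1] / 2 - 1)
  expect_gt(up[2], base[2])
})

test_that("threshold payoffs only move through the kept term off the boundary", {
  g <- pgg_game(c(24, 24), c(1, 1), reward_threshold(theta = 24, r = 20))
  expect_equal(payoffs(g, c(13, 12)) - payoffs(g, c(12, 12)), c(-1, 0))
  expect_equal(payoffs(g, c(5, 5)) - payoffs(g, c(4, 5)), c(-1, 0))
})

test_that("threshold crossing is decided exactly for fractional productivities", {
  # theta = 38.4 with p = 1.6: C = 1.6 * 24 = 38.4 must count as met
  g <- make_treatment("threshold", "FE")
  expect_equal(payoffs(g, c(24, 0)), c(20, 44))
  expect_equal(payoffs(g, c(23, 0)), c(1, 24)) # C = 36.8 < 38.4
})

test_that("social dilemma condition is 1 < p_i < n for all players", {
  expect_true(is_social_dilemma(pgg_game(c(24, 24), c(1.6, 1.6))))
  expect_false(is_social_dilemma(pgg_game(c(24, 24), c(1.0, 1.6))))
  expect_false(is_social_dilemma(pgg_game(c(24, 24), c(2.0, 1.2))))
  expect_true(is_social_dilemma(make_treatment("linear", "AI", n = 4)))
  expect_error(is_social_dilemma(make_treatment("threshold", "FE")),
               "linear")
})

test_that("treatment factory bakes in the published parameters", {
  fe <- make_treatment("linear", "FE")
  expect_equal(fe$e, c(24L, 24L))
  expect_equal(fe$p, c(1.6, 1.6))
  expect_equal(fe$reward$kind, "linear")

  ei <- make_treatment("linear", "EI")
  expect_equal(ei$e, c(36L, 12L))

  # endowments normalized to 48 and mean productivity 1.6 in all two-player
  # linear treatments
  for (sc in c("FE", "EI", "PI", "AI", "MI")) {
    g <- make_treatment("linear", sc)
    expect_equal(sum(g$e), 48)
    expect_equal(mean(g$p), 1.6)
    expect_true(is_social_dilemma(g))
  }

  # threshold default theta = sum(p e) / 2, r = 20
  thr <- make_treatment("threshold", "FE", overrides = list(p = c(1, 1)))
  expect_equal(thr$reward$theta, 24)
  expect_equal(thr$reward$r, 20)
  for (sc in c("FE", "EI", "PI", "AI", "MI")) {
    g <- make_treatment("threshold", sc)
    expect_equal(g$reward$theta, sum(g$p * g$e) / 2)
  }
})

test_that("missing registry entries raise a named unspecified-parameter error", {
  expect_error(make_treatment("linear", "EI", n = 4), "unspecified-parameter")
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("treatments:",
               "  - {game_type: linear, scenario: PI, n_players: 2, e: [24, 24], p: FIG1}"),
             tmp)
  expect_error(
    make_treatment("linear", "PI", registry = treatment_registry(tmp)),
    "unspecified-parameter.*'p'")
  expect_silent(
    g <- make_treatment("linear", "PI", overrides = list(p = c(1.8, 1.4)),
                        registry = treatment_registry(tmp)))
  expect_equal(g$p, c(1.8, 1.4))
})

test_that("productivities are stored as exact rationals", {
  g <- make_treatment("linear", "FE")
  expect_equal(g$p_num, c(8, 8))
  expect_equal(g$p_den, 5)
  ai <- make_treatment("linear", "AI")
  expect_equal(ai$p_num / ai$p_den, c(1.9, 1.3))
})
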