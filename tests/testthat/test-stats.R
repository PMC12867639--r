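make_trace <- function(spec, cc) {
  pp <- t(apply(cc, 1, function(row) payoffs(spec, row)))
  structure(list(contributions = cc, payoffs = pp, game = spec),
            class = "pgg_trace")
}

test_that("group relative contribution and surplus match hand arithmetic", {
  fe <- make_treatment("linear", "FE")
  full <- make_trace(fe, matrix(24L, 20, 2))
  none <- make_trace(fe, matrix(0L, 20, 2))
  expect_equal(group_relative_contribution(full), 1)
  expect_equal(group_relative_contribution(none), 0)
  expect_equal(group_overall_surplus(full), 0.6) # (76.8 - 48) / 48
  expect_equal(group_overall_surplus(none), 0)

  ei <- make_treatment("linear", "EI")
  half <- make_trace(ei, matrix(rep(c(18L, 6L), each = 20), 20, 2))
  expect_equal(group_relative_contribution(half), 0.5)

  toy <- pgg_game(c(24, 24), c(1, 1), reward_threshold(24, 20))
  tr <- make_trace(toy, matrix(12L, 20, 2))
  expect_equal(group_overall_surplus(tr), 1 / 3) # (64 - 48) / 48
  expect_equal(success_rate(tr), 1)
})

test_that("success rate counts threshold-meeting rounds", {
  toy <- pgg_game(c(24, 24), c(1, 1), reward_threshold(24, 20))
  alt <- make_trace(toy, matrix(rep(c(12L, 12L, 0L, 0L), 5), 20, 2, byrow = TRUE))
  expect_equal(success_rate(alt), 0.5)
  expect_equal(success_rate(make_trace(toy, matrix(0L, 5, 2))), 0)
  expect_error(success_rate(make_trace(make_treatment("linear", "FE"),
                                       matrix(0L, 5, 2))), "threshold")
})

test_that("Gini coefficient: pairwise mean-difference form, scale invariant", {
  expect_equal(gini(c(24, 24)), 0)
  expect_equal(gini(c(36, 12)), 0.25)
  expect_equal(gini(c(48, 0)), 0.5)
  set.seed(61)
  x <- runif(6, 0, 10)
  expect_equal(gini(3.7 * x), gini(x))
  expect_error(gini(c(0, 0)), "undefined")
  # matches the mean-absolute-difference definition on a random vector
  n <- length(x)
  expect_equal(gini(x), sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x)))
})

test_that("role contributions report absolute and relative means", {
  ei <- make_treatment("linear", "EI")
  tr <- make_trace(ei, matrix(rep(c(18L, 9L), each = 10), 10, 2))
  rc <- role_contributions(tr)
  expect_equal(rc$mean_contribution, c(18, 9))
  expect_equal(rc$mean_relative_contribution, c(0.5, 0.75))
})

test_that("full-contribution fraction counts all-endowment rounds", {
  ai <- make_treatment("linear", "AI")
  cc <- matrix(rep(c(36L, 12L), each = 20), 20, 2)
  cc[1:10, 1] <- 0L
  expect_equal(full_contribution_fraction(make_trace(ai, cc)), 0.5)
  expect_equal(full_contribution_fraction(make_trace(ai, matrix(0L, 4, 2))), 0)
})

test_that("lag-1 reciprocity is 1 for matching and -1 for anti-matching play", {
  fe <- make_treatment("linear", "FE")
  cc <- matrix(0L, 10, 2)
  cc[1, ] <- c(5L, 17L)
  for (t in 2:10) {
    cc[t, 1] <- cc[t - 1, 2]
    cc[t, 2] <- cc[t - 1, 1]
  }
  expect_equal(reciprocity_lag_correlation(make_trace(fe, cc)), c(1, 1))
  anti <- matrix(0L, 10, 2)
  anti[1, ] <- c(3L, 20L)
  for (t in 2:10) {
    anti[t, 1] <- 24L - anti[t - 1, 2]
    anti[t, 2] <- 24L - anti[t - 1, 1]
  }
  expect_equal(reciprocity_lag_correlation(make_trace(fe, anti)), c(-1, -1))
  # constant series: undefined, reported as NA
  expect_true(all(is.na(
    reciprocity_lag_correlation(make_trace(fe, matrix(12L, 10, 2))))))
  # independent series: near zero
  set.seed(62)
  rnd <- matrix(sample(0:24, 4000, replace = TRUE), 2000, 2)
  expect_lt(max(abs(reciprocity_lag_correlation(make_trace(fe, rnd)))), 0.08)
})

test_that("first/last trend windows average group relative contribution", {
  fe <- make_treatment("linear", "FE")
  const <- make_trace(fe, matrix(12L, 20, 2))
  tf <- trend_first_last(const)
  expect_equal(unname(tf["first"]), unname(tf["last"]))
  rising <- make_trace(fe, cbind(0:19, 0:19))
  tf <- trend_first_last(rising)
  expect_gt(tf[["last"]], tf[["first"]])
  expect_equal(tf[["first"]], mean(0:4) * 2 / 48)
  expect_error(trend_first_last(make_trace(fe, matrix(1L, 8, 2))), "at least")
})

test_that("linear GOS identity and threshold accounting identity hold", {
  set.seed(63)
  for (k in 1:10) {
    lin <- make_treatment("linear", "AI")
    cc <- cbind(sample(0:36, 15, TRUE), sample(0:12, 15, TRUE))
    tr <- make_trace(lin, cc)
    expect_equal(group_overall_surplus(tr),
                 sum((lin$p - 1) * colMeans(cc)) / sum(lin$e))
    thr <- make_treatment("threshold", "MI")
    cc2 <- cbind(sample(0:36, 15, TRUE), sample(0:12, 15, TRUE))
    tr2 <- make_trace(thr, cc2)
    expect_equal(success_rate(tr2) * 2 * thr$reward$r - sum(colMeans(cc2)),
                 sum(thr$e) * group_overall_surplus(tr2))
  }
})

test_that("statistics from round records average within groups then across", {
  fe <- make_treatment("linear", "FE")
  tr1 <- make_trace(fe, matrix(24L, 20, 2)) # grc 1
  tr2 <- make_trace(fe, matrix(0L, 20, 2))  # grc 0
  df <- rbind(as_round_records(tr1, group_id = 1),
              as_round_records(tr2, group_id = 2))
  expect_equal(group_relative_contribution(df), 0.5)
  expect_equal(group_overall_surplus(df), 0.3)
  rc <- role_contributions(df)
  expect_equal(rc$mean_contribution, c(12, 12))
  sm <- group_summary(df)
  expect_equal(sm$gini_endowments, 0)
  expect_equal(sm$full_contribution_fraction, 0.5)
})

test_that("group summary covers both game types", {
  thr <- make_treatment("threshold", "AI")
  tr <- make_trace(thr, matrix(rep(c(18L, 6L), each = 20), 20, 2))
  sm <- group_summary(tr)
  expect_equal(sm$success_rate, 1) # C = 42 = theta exactly
  expect_equal(sm$gini_endowments, 0.25)
  expect_equal(sm$group_overall_surplus,
               (sum(payoffs(thr, c(18, 6))) - 48) / 48)
  lin_sm <- group_summary(make_trace(make_treatment("linear", "FE"),
                                     matrix(12L, 20, 2)))
  expect_true(is.na(lin_sm$success_rate))

  # threshold round records carry enough information (reward paid or not)
  # to recover the success rate without the game spec
  df <- as_round_records(tr)
  expect_equal(success_rate(df), 1)
  expect_equal(group_summary(df)$success_rate, 1)
  miss <- make_trace(thr, matrix(rep(c(2L, 1L), each = 20), 20, 2))
  expect_equal(success_rate(as_round_records(miss)), 0)
})
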