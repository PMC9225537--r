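make_pairs <- function() {
  expand.grid(point = 1:4, group = 1:6)[, c("group", "point")] |>
    transform(delta_i_pct = ave(group, group, FUN = seq_along))
}

test_that("discrimination rates aggregate per pair, delta, and group", {
  pairs <- data.frame(group = c(1, 1, 2), point = c(1, 2, 1),
                      delta_i_pct = c(1, 2, 1))
  mk <- function(resp) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      data.frame(participant = sprintf("P%d", 1:5),
                 group = pairs$group[i], point = pairs$point[i],
                 kind = "metamer", delta_i_pct = pairs$delta_i_pct[i],
                 response = resp)))
  }
  all_diff <- discrimination_rates(mk("different"))
  expect_true(all(all_diff$per_pair$rate_pct == 100))
  expect_true(all(all_diff$per_group$mean_rate_pct == 100))
  all_same <- discrimination_rates(mk("same"))
  expect_true(all(all_same$per_pair$rate_pct == 0))
  # hand-counted mixed table: 5 participants x 2 trials, 7 of 10 "different"
  t7 <- data.frame(participant = rep(sprintf("P%d", 1:5), each = 2),
                   group = 3, point = 2, kind = "metamer", delta_i_pct = 3,
                   response = rep(c("different", "same"), c(7, 3)))
  s <- discrimination_rates(t7)
  expect_equal(s$per_pair$rate_pct, 70)
  expect_equal(s$per_pair$n_trials, 10)
})

test_that("aggregation is permutation invariant and mean consistent", {
  pairs <- make_pairs()
  trials <- simulate_responses(pairs, seed = 42)
  s1 <- discrimination_rates(trials)
  set.seed(1)
  s2 <- discrimination_rates(trials[sample(nrow(trials)), ])
  expect_equal(s1$per_pair, s2$per_pair)
  expect_equal(s1$dummy_rate_pct, s2$dummy_rate_pct)
  # per-group average of a constant-rate table is that constant
  const <- trials[trials$kind == "metamer", ]
  const$response <- "different"
  sc <- discrimination_rates(const)
  expect_true(all(sc$per_group$mean_rate_pct == 100))
})

test_that("trial validation reports offending rows", {
  pairs <- data.frame(group = 1, point = 1, delta_i_pct = 1)
  trials <- simulate_responses(pairs, seed = 1)
  bad <- trials
  bad$response[3] <- "dunno"
  expect_error(discrimination_rates(bad), "row 3")
  expect_error(discrimination_rates(trials[0, ]), "empty")
  bad2 <- trials
  bad2$delta_i_pct[bad2$kind == "dummy"][1] <- 2
  expect_error(discrimination_rates(bad2), "dummy")
})

test_that("trial tables round-trip through CSV", {
  pairs <- make_pairs()
  trials <- simulate_responses(pairs, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(trials, f)
  expect_equal(read_trials_csv(f), trials)
})

test_that("the trend statistic captures monotone and flat rate patterns", {
  mk_summary <- function(rates) {
    pairs <- data.frame(group = 1, point = 1:4, delta_i_pct = 1:4)
    trials <- do.call(rbind, lapply(1:4, function(i)
      data.frame(participant = sprintf("P%d", 1:100), group = 1,
                 point = i, kind = "metamer", delta_i_pct = i,
                 response = rep(c("different", "same"),
                                c(rates[i], 100 - rates[i])))))
    discrimination_rates(trials)
  }
  up <- trend_statistic(mk_summary(c(10, 30, 60, 90)))
  expect_equal(up$spearman_rho, 1)
  expect_gt(up$slope, 0)
  flat <- trend_statistic(mk_summary(c(40, 40, 40, 40)))
  expect_true(flat$undefined)
  expect_equal(flat$slope, 0)
})

test_that("the response generator is deterministic and honest about its probabilities", {
  pairs <- make_pairs()
  t1 <- simulate_responses(pairs, seed = 9)
  t2 <- simulate_responses(pairs, seed = 9)
  expect_identical(t1, t2)
  # zero slope: metamer and dummy responses are indistinguishable
  pr0 <- data.frame(group = 1, point = 1, delta_i_pct = 3)
  big <- simulate_responses(pr0, n_participants = 2500, n_trials = 2,
                            guess_rate = 0.15, slope = 0, seed = 5)
  met <- big[big$kind == "metamer", ]
  dum <- big[big$kind == "dummy", ]
  pt <- stats::prop.test(c(sum(met$response == "different"),
                           sum(dum$response == "different")),
                         c(nrow(met), nrow(dum)))
  expect_gt(pt$p.value, 0.01)
  # large-n rate matches the generating probability at delta = 4
  pr4 <- data.frame(group = 1, point = 1, delta_i_pct = 4)
  big4 <- simulate_responses(pr4, n_participants = 5000, n_trials = 2,
                             guess_rate = 0.1, slope = 1.5, seed = 6)
  p_gen <- 0.1 + 0.9 * (2 * (stats::plogis(1.5 * 4) - 0.5))
  met4 <- big4[big4$kind == "metamer", ]
  expect_lt(abs(mean(met4$response == "different") - p_gen), 0.01)
})

test_that("simulate-then-analyse recovers the generating psychometric function", {
  pairs <- make_pairs()
  trials <- simulate_responses(pairs, n_participants = 120, n_trials = 2,
                               guess_rate = 0.1, slope = 1.2, seed = 21)
  s <- discrimination_rates(trials)
  for (i in seq_len(nrow(s$per_delta))) {
    d <- s$per_delta$delta_i_pct[i]
    p_gen <- 0.1 + 0.9 * (2 * (stats::plogis(1.2 * d) - 0.5))
    n <- sum(trials$kind == "metamer" & trials$delta_i_pct == d)
    se <- sqrt(p_gen * (1 - p_gen) / n)
    expect_lt(abs(s$per_delta$mean_rate_pct[i] / 100 - p_gen), 4 * se + 1e-9)
  }
  # dummy rate recovers the guess rate
  n_dum <- sum(trials$kind == "dummy")
  expect_lt(abs(s$dummy_rate_pct / 100 - 0.1),
            4 * sqrt(0.1 * 0.9 / n_dum))
})

test_that("a positive psychometric slope is detected across seeds", {
  pairs <- make_pairs()
  hits <- 0
  for (seed in 1:200) {
    trials <- simulate_responses(pairs, n_participants = 5, n_trials = 2,
                                 guess_rate = 0.1, slope = 1.5, seed = seed)
    tr <- trend_statistic(discrimination_rates(trials))
    hits <- hits + (!tr$undefined && tr$slope > 0)
  }
  expect_gte(hits / 200, 0.95)
})
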