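test_that("conditional probabilities on deterministic patterns", {
  alt <- tibble::tibble(participant = "p1", trial = 1:20,
                        choice = rep(c(1L, 0L), 10))
  cp <- conditional_probabilities(alt, lags = 1:2)
  expect_equal(cp$p[cp$lag == 1], 0)
  expect_equal(cp$p[cp$lag == 2], 1)

  ones <- tibble::tibble(participant = "p1", trial = 1:10, choice = 1L)
  cp1 <- conditional_probabilities(ones, lags = 1:3)
  expect_true(all(cp1$p == 1))

  # no conditioning trials: missing with zero count
  zeros <- tibble::tibble(participant = "p1", trial = 1:10, choice = 0L)
  cp0 <- conditional_probabilities(zeros, lags = 1)
  expect_true(is.na(cp0$p))
  expect_equal(cp0$n, 0L)
})

test_that("pooled and per-participant variants are both available", {
  d <- simulate_fair_coin(500, 4, seed = 1)
  pooled <- conditional_probabilities(d, lags = 1:3)
  per <- conditional_probabilities(d, lags = 1:3, by = "participant")
  expect_equal(nrow(pooled), 3)
  expect_equal(nrow(per), 12)
  # pooled counts are the sum of participant counts
  expect_equal(pooled$n, tapply(per$n, per$lag, sum, simplify = TRUE),
               ignore_attr = TRUE)
})

test_that("heads-count distribution is a normalised window histogram", {
  ones <- tibble::tibble(participant = "p1", trial = 1:30, choice = 1L)
  hc <- heads_count_distribution(ones)
  expect_equal(sum(hc$prob), 1)
  expect_equal(hc$prob[hc$heads == 10], 1)

  coin <- simulate_fair_coin(1e5, 1, seed = 2)
  hc2 <- heads_count_distribution(coin)
  expect_equal(sum(hc2$prob), 1)
  # chance mass at 5 is C(10,5)/2^10 = 0.2461
  expect_within(hc2$prob[hc2$heads == 5], choose(10, 5) / 2^10, 0.02)

  short <- tibble::tibble(participant = "p1", trial = 1:5, choice = 1L)
  expect_error(heads_count_distribution(short), "shorter than the window")
})

test_that("balance-biased generators over-produce balanced windows", {
  # strong negative sum-dependence: completes the local balance
  d <- simulate_logistic_agent(c(0, rep(-0.8, 9)), 2e4, seed = 3)
  hc <- heads_count_distribution(d)
  expect_gt(hc$prob[hc$heads == 5], choose(10, 5) / 2^10)
})

test_that("alternation by run length matches hand traces", {
  d <- tibble::tibble(participant = "p1", trial = 1:4,
                      choice = c(0L, 0L, 0L, 1L))
  rl <- alternation_by_run_length(d)
  # t=2 (RL 1, repeat), t=3 (RL 2, repeat), t=4 (RL 3, alternate)
  expect_equal(rl$run_length, 1:3)
  expect_equal(rl$n, rep(1L, 3))
  expect_equal(rl$p_alternate, c(0, 0, 1))

  alt <- tibble::tibble(participant = "p1", trial = 1:20,
                        choice = rep(c(0L, 1L), 10))
  rla <- alternation_by_run_length(alt)
  expect_equal(rla$run_length, 1L)
  expect_equal(rla$p_alternate, 1)
})

test_that("run-length tallies total N - 1 and the coin is memoryless", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    d <- simulate_fair_coin(n, 1)
    rl <- alternation_by_run_length(d)
    expect_equal(sum(rl$n), n - 1L)
  }
  big <- simulate_fair_coin(5e4, 1, seed = 5)
  rlb <- alternation_by_run_length(big)
  well <- rlb[rlb$n >= 200, ]
  for (i in seq_len(nrow(well))) {
    expect_within(well$p_alternate[i], 0.5, 3.5 * sqrt(0.25 / well$n[i]))
  }
})

test_that("Monte-Carlo chance bands centre on the analytic null", {
  band <- chance_band("heads_count", n_trials = 1000, n_sequences = 3,
                      n_sims = 200, seed = 6)
  expect_within(band$null_mean[band$heads == 5], choose(10, 5) / 2^10, 0.005)
  expect_true(all(band$lower <= band$null_mean & band$null_mean <= band$upper))

  bandc <- chance_band("conditional", n_trials = 2000, n_sequences = 2,
                       n_sims = 150, seed = 7, lags = 1:3)
  expect_true(all(abs(bandc$null_mean - 0.5) < 0.01))

  # band width shrinks roughly like 1/sqrt(n_trials per sim)
  narrow <- chance_band("conditional", n_trials = 8000, n_sequences = 2,
                        n_sims = 150, seed = 7, lags = 1)
  expect_lt(narrow$upper - narrow$lower, bandc$upper[1] - bandc$lower[1])
})

test_that("a lag-3 refit reproduces the qualitative signatures", {
  # population with alternation bias at lag 1 and balance pressure:
  # fit L = 3 per participant, simulate from the fits, and recover the
  # same direction of deviation from chance
  pop <- simulate_population(8, 1500, beta_mean = c(0, -0.6, -0.2, -0.2),
                             beta_sd = c(0.05, 0.2, 0.1, 0.1), seed = 8)
  fits <- fit_population(pop$data, 3)
  resim <- dplyr::bind_rows(purrr::map(
    split(fits, fits$participant),
    function(f) {
      simulate_logistic_agent(f$estimate[order(f$lag)], 1500,
                              participant = f$participant[1])
    }))
  rl_obs <- alternation_by_run_length(pop$data)
  rl_sim <- alternation_by_run_length(resim)
  expect_gt(rl_obs$p_alternate[rl_obs$run_length == 1], 0.55)
  expect_gt(rl_sim$p_alternate[rl_sim$run_length == 1], 0.55)
  hc_sim <- heads_count_distribution(resim)
  expect_gt(hc_sim$prob[hc_sim$heads == 5], choose(10, 5) / 2^10)
})
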