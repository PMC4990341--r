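make_fits <- function(m) {
  # wrap a participants x lags matrix as a population-fits tibble
  tibble::tibble(
    participant = rep(sprintf("p%02d", seq_len(nrow(m))), ncol(m)),
    term = rep(paste0("beta", seq_len(ncol(m)) - 1), each = nrow(m)),
    lag = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    estimate = as.vector(m),
    std.error = 0.1, conf.low = as.vector(m) - 0.2,
    conf.high = as.vector(m) + 0.2, p.value = 0.5, converged = TRUE
  )
}

test_that("summaries follow their definitions on hand-made columns", {
  s <- summarize_population(make_fits(cbind(c(1, -1), c(-0.4, -0.4))))
  expect_equal(s$mu, c(0, -0.4))
  expect_equal(s$qmean, c(1, 0.4))
  expect_equal(s$snr[1], 0)
  expect_equal(s$snr[2], Inf)  # zero spread marker, not a crash
})

test_that("the quadratic-mean identity holds to machine precision", {
  set.seed(1)
  for (i in 1:10) {
    m <- matrix(rnorm(7 * 3, sd = 2), 7, 3)
    colnames(m) <- paste0("beta", 0:2)
    s <- summarize_population(make_fits(m))
    n <- nrow(m)
    expect_equal(s$qmean^2, s$mu^2 + s$sigma^2 * (n - 1) / n,
                 tolerance = 1e-12)
  }
})

test_that("per-participant fits recover population structure", {
  pop <- simulate_population(12, 800, beta_mean = c(0, 0, 0, -0.5),
                             beta_sd = c(0.05, 0.9, 0.1, 0.05), seed = 2)
  fits <- fit_population(pop$data, 3)
  expect_equal(dplyr::n_distinct(fits$participant), 12)
  s <- summarize_population(fits)
  # heterogeneous lag 1: large magnitude, small mean -> low SNR;
  # common lag 3: high SNR
  expect_gt(s$qmean[s$lag == 1], 0.5)
  expect_gt(s$snr[s$lag == 3], s$snr[s$lag == 1])

  # sign-split: strong beta1 on both sides of zero
  b1 <- fits$estimate[fits$lag == 1]
  expect_gt(sum(b1 > 0.3), 0)
  expect_gt(sum(b1 < -0.3), 0)

  # identical-generator population: rows agree within sampling error
  pop0 <- simulate_population(5, 800, beta_mean = c(0, -0.6),
                              beta_sd = c(0, 0), seed = 3)
  f0 <- fit_population(pop0$data, 1)
  expect_lt(sd(f0$estimate[f0$lag == 1]), 0.15)
})

test_that("bootstrap intervals behave and respect the correction", {
  m <- cbind(beta0 = rep(0.7, 6), beta1 = c(-1, 1, -0.5, 0.5, -0.2, 0.2))
  ci <- bootstrap_ci(make_fits(m), statistics = "mu", B = 50, seed = 4)
  expect_equal(ci$conf.low[ci$lag == 0], 0.7)   # constant column: zero width
  expect_equal(ci$conf.high[ci$lag == 0], 0.7)
  expect_true(all(ci$conf.low <= ci$estimate & ci$estimate <= ci$conf.high))
  expect_warning(bootstrap_ci(make_fits(m), B = 1, seed = 5), "degenerate")
})

test_that("bootstrap mu intervals cover the truth at about nominal rate", {
  set.seed(6)
  truth_mu <- 0.4
  cover <- logical(200)
  for (i in seq_along(cover)) {
    m <- cbind(beta0 = rnorm(10, truth_mu, 0.5))
    ci <- bootstrap_ci(make_fits(m), statistics = "mu", B = 200,
                       m_tests = 1)
    cover[i] <- ci$conf.low <= truth_mu && truth_mu <= ci$conf.high
  }
  # percentile bootstrap at n = 10 undercovers slightly; allow binomial
  # error around ~0.92 +/- 3 * 0.02
  expect_gt(mean(cover), 0.85)
})

test_that("task comparison covers zero for identical populations", {
  set.seed(7)
  m <- matrix(rnorm(10 * 2), 10, 2)
  colnames(m) <- c("beta0", "beta1")
  cmp <- compare_tasks(make_fits(m), make_fits(m), B = 100, seed = 8)
  mu_rows <- cmp[cmp$statistic == "mu", ]
  expect_true(all(mu_rows$conf.low <= 0 & 0 <= mu_rows$conf.high))
  expect_true(all(mu_rows$diff == 0))

  # constructed ordering: homogeneous strong beta1 vs mean-zero heterogeneous
  a <- cbind(beta0 = rnorm(12, 0, 0.1), beta1 = rnorm(12, 3, 0.3))
  b <- cbind(beta0 = rnorm(12, 0, 0.1), beta1 = rnorm(12, 0, 1.5))
  cmp2 <- compare_tasks(make_fits(a), make_fits(b), B = 100, seed = 9)
  expect_gt(cmp2$diff[cmp2$statistic == "mu" & cmp2$lag == 1], 0)
  expect_gt(cmp2$diff[cmp2$statistic == "snr" & cmp2$lag == 1], 0)

  expect_error(compare_tasks(make_fits(m), make_fits(a[, 1, drop = FALSE])),
               "lag ranges")
})

test_that("non-converged participants are excluded with a warning", {
  m <- matrix(rnorm(8), 4, 2)
  colnames(m) <- c("beta0", "beta1")
  fits <- make_fits(m)
  fits$converged[fits$participant == "p01"] <- FALSE
  expect_warning(s <- summarize_population(fits), "excluded")
  expect_equal(s$n_participants[1], 3)
})
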