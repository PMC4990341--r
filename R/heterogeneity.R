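## Population heterogeneity of sequential effects: per-participant
## coefficient estimation and the cross-participant summaries -- mean
## mu(beta_k), quadratic mean sqrt(mean(beta_k^2)), SD sigma(beta_k) and
## SNR = |mu| / sigma -- with participant-level bootstrap intervals.
##
## A high SNR means the population shares a common effect; a large quadratic
## mean with near-zero mu is the signature of strong but heterogeneous
## effects that average out in a pooled analysis.

#' Fit the logistic model to every participant separately
#'
#' @param data A choice tibble.
#' @param L Model horizon.
#' @param alpha Nominal level for per-coefficient intervals.
#' @param m_tests Bonferroni denominator (defaults to `L + 1`).
#' @return A tibble with one row per participant x coefficient:
#'   `participant`, `term`, `lag`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`, `converged`.  Non-converged rows are flagged,
#'   not dropped; [summarize_population()] excludes them with a warning.
#' @export
fit_population <- function(data, L, alpha = 0.05, m_tests = NULL) {
  data <- validate_sequences(data)
  fits <- purrr::map(split_participants(data), function(d) {
    des <- build_lag_design(d, L)
    fit <- fit_logistic_mle(des, alpha = alpha, m_tests = m_tests)
    out <- tidy(fit)
    out$converged <- fit$converged
    out
  })
  res <- dplyr::bind_rows(fits, .id = "participant")
  res$lag <- as.integer(sub("^beta", "", res$term))
  dplyr::relocate(res, "participant", "term", "lag")
}

## participants x lags matrix of estimates from the long fits table,
## participants with any non-converged coefficient removed.
coef_matrix <- function(fits, warn = TRUE) {
  bad <- unique(fits$participant[!fits$converged])
  if (length(bad) > 0) {
    if (warn) warning(length(bad), " participant(s) with non-converged fits ",
                      "excluded: ", paste(head(bad, 5), collapse = ", "),
                      call. = FALSE)
    fits <- dplyr::filter(fits, !(.data$participant %in% bad))
  }
  wide <- tidyr::pivot_wider(fits[c("participant", "term", "estimate")],
                             names_from = "term", values_from = "estimate")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant
  m[, order(as.integer(sub("^beta", "", colnames(m)))), drop = FALSE]
}

summary_stats <- function(m) {
  n <- nrow(m)
  mu <- unname(colMeans(m))
  qmean <- unname(sqrt(colMeans(m^2)))
  sigma <- unname(apply(m, 2, sd))  # sample (n - 1) convention
  tibble::tibble(
    term = colnames(m),
    lag = as.integer(sub("^beta", "", colnames(m))),
    mu = mu, qmean = qmean, sigma = sigma,
    snr = ifelse(sigma > 0, abs(mu) / sigma, Inf),
    n_participants = n
  )
}

#' Summarise a population of per-participant coefficients
#'
#' Columnwise mean `mu`, quadratic mean `qmean` = sqrt(mean(beta^2)), sample
#' SD `sigma` (n - 1 denominator) and `snr` = |mu| / sigma for each lag.
#' Under this convention `qmean^2 = mu^2 + sigma^2 * (n - 1) / n` exactly.
#' A zero-SD column yields an infinite SNR marker rather than an error.
#'
#' @param fits A population-fits tibble from [fit_population()] (or
#'   [residual_sequential_effects()]).
#' @return A `heterogeneity_summary` tibble, one row per lag.
#' @export
summarize_population <- function(fits) {
  m <- coef_matrix(fits)
  if (nrow(m) < 2) stop("need >= 2 converged participants", call. = FALSE)
  out <- summary_stats(m)
  class(out) <- c("heterogeneity_summary", class(out))
  out
}

#' Bootstrap confidence intervals for population summaries
#'
#' Resamples participants (not trials) with replacement `B` times and returns
#' percentile intervals at the Bonferroni-corrected level
#' `1 - alpha / m_tests` for each requested statistic and lag.
#'
#' @param fits A population-fits tibble.
#' @param statistics Which of `"mu"`, `"qmean"`, `"sigma"`, `"snr"`.
#' @param B Number of bootstrap resamples.
#' @param alpha Nominal level.
#' @param m_tests Bonferroni denominator; defaults to the number of lags.
#' @param seed Optional integer seed.
#' @return A tibble `lag`, `statistic`, `estimate`, `conf.low`, `conf.high`.
#' @export
bootstrap_ci <- function(fits, statistics = c("mu", "qmean", "sigma", "snr"),
                         B = 100, alpha = 0.05, m_tests = NULL, seed = NULL) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  m <- coef_matrix(fits)
  if (nrow(m) < 2) stop("need >= 2 converged participants", call. = FALSE)
  if (B < 2) warning("B < 2 gives a degenerate bootstrap interval",
                     call. = FALSE)
  if (is.null(m_tests)) m_tests <- ncol(m)
  if (!is.null(seed)) set.seed(seed)
  level <- 1 - bonferroni_level(alpha, m_tests)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  point <- summary_stats(m)
  boots <- purrr::map(seq_len(B), function(b) {
    mb <- m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
    summary_stats(mb)
  })
  boots <- dplyr::bind_rows(boots)
  long <- tidyr::pivot_longer(boots, dplyr::all_of(statistics),
                              names_to = "statistic", values_to = "value")
  ci <- dplyr::summarise(
    dplyr::group_by(long, .data$lag, .data$statistic),
    conf.low = quantile(.data$value, probs[1], names = FALSE, type = 7),
    conf.high = quantile(.data$value, probs[2], names = FALSE, type = 7),
    .groups = "drop"
  )
  pt <- tidyr::pivot_longer(point, dplyr::all_of(statistics),
                            names_to = "statistic", values_to = "estimate")
  dplyr::left_join(pt[c("lag", "statistic", "estimate")], ci,
                   by = c("lag", "statistic"))
}

#' Compare two populations' heterogeneity summaries
#'
#' Per-lag differences (A minus B) in `mu`, `qmean`, `sigma` and `snr`
#' between two populations of per-participant coefficients, with bootstrap
#' intervals from independent resampling of each population.  Used to
#' contrast sequential effects across tasks (e.g. operant learning vs
#' sequence generation).
#'
#' @param fits_a,fits_b Population-fits tibbles covering the same lags.
#' @param B Number of bootstrap resamples.
#' @param alpha Interval level (uncorrected by default; pass
#'   `m_tests` to Bonferroni-correct).
#' @param m_tests Bonferroni denominator (default 1).
#' @param seed Optional integer seed.
#' @return A tibble `lag`, `statistic`, `diff`, `conf.low`, `conf.high`.
#' @export
compare_tasks <- function(fits_a, fits_b, B = 100, alpha = 0.05,
                          m_tests = 1, seed = NULL) {
  ma <- coef_matrix(fits_a); mb <- coef_matrix(fits_b)
  if (!identical(colnames(ma), colnames(mb))) {
    stop("populations cover different lag ranges", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  level <- 1 - bonferroni_level(alpha, m_tests)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stats <- c("mu", "qmean", "sigma", "snr")
  diff_stats <- function(xa, xb) {
    a <- tidyr::pivot_longer(summary_stats(xa), dplyr::all_of(stats),
                             names_to = "statistic", values_to = "va")
    b <- tidyr::pivot_longer(summary_stats(xb), dplyr::all_of(stats),
                             names_to = "statistic", values_to = "vb")
    out <- dplyr::left_join(a[c("lag", "statistic", "va")],
                            b[c("lag", "statistic", "vb")],
                            by = c("lag", "statistic"))
    out$diff <- out$va - out$vb
    out[c("lag", "statistic", "diff")]
  }
  point <- diff_stats(ma, mb)
  boots <- purrr::map(seq_len(B), function(b) {
    diff_stats(ma[sample.int(nrow(ma), replace = TRUE), , drop = FALSE],
               mb[sample.int(nrow(mb), replace = TRUE), , drop = FALSE])
  })
  boots <- dplyr::bind_rows(boots)
  ci <- dplyr::summarise(
    dplyr::group_by(boots, .data$lag, .data$statistic),
    conf.low = quantile(.data$diff, probs[1], names = FALSE),
    conf.high = quantile(.data$diff, probs[2], names = FALSE),
    .groups = "drop"
  )
  dplyr::left_join(point, ci, by = c("lag", "statistic"))
}
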