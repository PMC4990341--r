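## The reward-augmented lagged choice model for operant sessions:
## DQ_t = beta0 + sum_k s_{t-k} (alpha_k r_{t-k} + beta_k).
## alpha_k load on the reward-by-action interaction (the "value" part,
## reducing to TD learning when alpha_k = gamma^k / T and beta = 0);
## beta_k are the residual, reward-independent sequential effects.

#' Fit the reward-augmented lagged choice model
#'
#' One joint maximum-likelihood logistic fit over the `2L + 1` regressors
#' (intercept, signed lags, signed-lag-by-reward interactions) of a design
#' built with `include_rewards = TRUE`.  Reward weights `alpha_1..alpha_L`
#' and sequential weights `beta_0..beta_L` are reported together.  A
#' rank-deficient design (e.g. constant rewards, which make the interaction
#' columns copies of the lag columns) is flagged with a warning naming the
#' collinear columns and the fit is marked unconverged.
#'
#' @inheritParams fit_logistic_mle
#' @param design A lag-design tibble with reward-lag columns.
#' @return An `rl_fit` object (also a `logistic_fit`); `tidy()` rows are
#'   `beta0..betaL, alpha1..alphaL`.
#' @export
fit_rl <- function(design, weights = NULL, alpha = 0.05, m_tests = NULL,
                   ridge = 0) {
  dm <- design_matrix(design, include_rewards = TRUE)
  L <- dm$L
  n <- length(dm$y)
  if (n < 2 * L + 2) stop("need at least 2L + 2 rows to fit ", 2 * L + 1,
                          " coefficients", call. = FALSE)
  if (length(unique(dm$y)) < 2) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  if (is.null(m_tests)) m_tests <- 2 * L + 1
  qrX <- qr(dm$X)
  collinear <- qrX$rank < ncol(dm$X)
  if (collinear) {
    dropped <- colnames(dm$X)[qrX$pivot[(qrX$rank + 1):ncol(dm$X)]]
    warning("collinear design columns: ", paste(dropped, collapse = ", "),
            "; estimates are not jointly identified", call. = FALSE)
  }
  nf <- newton_logistic(dm$X, dm$y, weights,
                        ridge = if (collinear && ridge == 0) 1e-6 else ridge)
  if (collinear) nf$converged <- FALSE
  terms <- c(paste0("beta", 0:L), paste0("alpha", seq_len(L)))
  logistic_fit_object(nf, terms, n, L, alpha, m_tests, has_alpha = TRUE)
}

#' Residual reward-independent sequential effects of an operant population
#'
#' Fits the reward-augmented model separately to every participant (blocks
#' pooled as stacked designs; lags never cross block boundaries) and returns
#' only the sequential `beta` coefficients, in the per-participant long
#' format that [summarize_population()] and [bootstrap_ci()] consume.  The
#' reward weights `alpha` are estimated jointly but excluded, so what remains
#' is the sequential dependence not explained by reward.
#'
#' @param data A choice tibble with rewards (and usually blocks).
#' @param L Model horizon.
#' @param alpha Nominal level for the per-coefficient intervals.
#' @param m_tests Bonferroni denominator (defaults to `2L + 1` fitted terms).
#' @return A population-fits tibble (`participant`, `term`, `lag`,
#'   `estimate`, ..., `converged`) restricted to `beta` terms.
#' @export
residual_sequential_effects <- function(data, L, alpha = 0.05,
                                        m_tests = NULL) {
  data <- validate_sequences(data)
  if (!("reward" %in% names(data))) {
    stop("operant data must have a `reward` column", call. = FALSE)
  }
  fits <- purrr::map(split_participants(data), function(d) {
    des <- build_lag_design(d, L, include_rewards = TRUE)
    fit <- fit_rl(des, alpha = alpha, m_tests = m_tests)
    out <- tidy(fit)
    out$converged <- fit$converged
    out
  })
  res <- dplyr::bind_rows(fits, .id = "participant")
  res <- dplyr::filter(res, grepl("^beta", .data$term))
  res$lag <- as.integer(sub("^beta", "", res$term))
  dplyr::relocate(res, "participant", "term", "lag")
}

split_participants <- function(data) {
  split(data, data$participant)
}
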