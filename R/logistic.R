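## Weighted maximum-likelihood estimation of the lagged logistic choice
## model, with Wald tests and Bonferroni-corrected confidence intervals.
##
## The solver is a damped Newton iteration on the weighted Bernoulli
## log-likelihood with an optional ridge penalty (used only to stabilise the
## near-degenerate discounted fits of the stationarity scan) and explicit
## separation handling: coefficients are capped at |beta| = 20 and the fit is
## flagged unconverged rather than crashing, so capped fits stay usable for
## prediction in cross-validation.

#' Logistic choice probability
#'
#' \eqn{\Pr(a_t = 1) = 1 / (1 + e^{-\Delta Q})}, numerically stable over the
#' full double range of the linear predictor.
#'
#' @param delta_q Linear predictor (finite; vectorised).
#' @return Probabilities in `(0, 1)`.
#' @export
choice_probability <- function(delta_q) {
  if (!is.numeric(delta_q) || any(is.na(delta_q))) {
    stop("`delta_q` must be numeric with no NA/NaN", call. = FALSE)
  }
  plogis(delta_q)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Nominal level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_level <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

## log Pr(y | eta) summed with weights, computed on the log scale.
bernoulli_loglik <- function(eta, y, w) {
  sum(w * ifelse(y == 1, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE)))
}

## Core damped-Newton solver on (X, y) with prior weights w.
## Returns beta, vcov, loglik, converged, separated.
newton_logistic <- function(X, y, w = NULL, ridge = 0, cap = 20,
                            tol = 1e-8, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  beta <- numeric(p)
  ll <- bernoulli_loglik(drop(X %*% beta), y, w) - ridge * sum(beta^2) / 2
  converged <- FALSE; separated <- FALSE
  H <- diag(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, w * (y - mu))) - ridge * beta
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    wt <- w * mu * (1 - mu)
    H <- crossprod(X, X * wt) + diag(ridge, p)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(solve(H + diag(1e-8, p), score), error = function(e) NULL)
      if (is.null(step)) break
    }
    ## halve the step until the penalised log-likelihood does not decrease
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      ll_new <- bernoulli_loglik(drop(X %*% beta_new), y, w) -
        ridge * sum(beta_new^2) / 2
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    beta <- beta_new; ll <- ll_new
    if (any(abs(beta) > cap)) {
      beta <- pmin(pmax(beta, -cap), cap)
      separated <- TRUE
      ll <- bernoulli_loglik(drop(X %*% beta), y, w) - ridge * sum(beta^2) / 2
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  wt <- w * mu * (1 - mu)
  Hfin <- crossprod(X, X * wt) + diag(ridge, p)
  vcov <- tryCatch(solve(Hfin), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov,
       loglik = bernoulli_loglik(eta, y, w),
       converged = converged && !separated, separated = separated)
}

logistic_fit_object <- function(nf, terms, n_obs, L, alpha, m_tests,
                                has_alpha = FALSE) {
  se <- sqrt(pmax(diag(nf$vcov), 0))
  level <- 1 - bonferroni_level(alpha, m_tests)
  z <- qnorm(1 - (1 - level) / 2)
  est <- nf$beta
  coef_tbl <- tibble::tibble(
    term = terms,
    estimate = est,
    std.error = se,
    conf.low = est - z * se,
    conf.high = est + z * se,
    p.value = 2 * pnorm(-abs(est / se))
  )
  structure(
    list(coefficients = coef_tbl, loglik = nf$loglik, n_obs = n_obs, L = L,
         converged = nf$converged, separated = nf$separated,
         alpha = alpha, m_tests = m_tests, has_alpha = has_alpha),
    class = c(if (has_alpha) "rl_fit", "logistic_fit")
  )
}

#' Fit the lagged logistic choice model by maximum likelihood
#'
#' Maximises the (optionally weighted) Bernoulli log-likelihood
#' \eqn{\sum_t w_t [a_t \log p_t + (1 - a_t)\log(1 - p_t)]} over
#' `beta0..betaL` for a signed-lag design (see [build_lag_design()]).
#' Standard errors come from the inverse observed information; confidence
#' intervals are reported at the Bonferroni-corrected level
#' `1 - alpha / m_tests`.  Passing a multi-participant design yields the
#' pooled (stacked-design) fit; histories never cross participant or block
#' boundaries because the design already respects them.
#'
#' @param design A lag-design tibble.
#' @param weights Optional non-negative per-row observation weights (finite,
#'   positive sum).
#' @param alpha Nominal significance level for the intervals.
#' @param m_tests Number of tests for the Bonferroni correction; defaults to
#'   the number of coefficients `L + 1`.
#' @param ridge Ridge penalty (off by default; used by the stationarity scan).
#' @return A `logistic_fit` object; see [tidy.logistic_fit()] and
#'   [glance.logistic_fit()].
#' @export
fit_logistic_mle <- function(design, weights = NULL, alpha = 0.05,
                             m_tests = NULL, ridge = 0) {
  dm <- design_matrix(design, include_rewards = FALSE)
  n <- length(dm$y)
  if (n < dm$L + 2) stop("need at least L + 2 rows to fit ", dm$L + 1,
                         " coefficients", call. = FALSE)
  if (length(unique(dm$y)) < 2) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  if (!is.null(weights)) {
    if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0) ||
        sum(weights) <= 0) {
      stop("`weights` must be finite, non-negative, with positive sum",
           call. = FALSE)
    }
  }
  if (is.null(m_tests)) m_tests <- dm$L + 1
  nf <- newton_logistic(dm$X, dm$y, weights, ridge = ridge)
  logistic_fit_object(nf, paste0("beta", 0:dm$L), n, dm$L, alpha, m_tests)
}

#' @export
print.logistic_fit <- function(x, ...) {
  kind <- if (x$has_alpha) "Reward-augmented lagged logistic fit"
          else "Lagged logistic fit"
  cat(kind, " (L = ", x$L, ", n = ", x$n_obs, ")\n", sep = "")
  if (!x$converged) {
    cat("  NOT converged", if (x$separated) " (separation: |beta| capped at 20)",
        "\n", sep = "")
  }
  cat("  log-likelihood: ", format(x$loglik), "\n", sep = "")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`).
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) x$coefficients

#' One-row model summary of a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A one-row tibble (`loglik`, `n_obs`, `L`, `converged`).
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_obs = x$n_obs, L = x$L,
                 converged = x$converged)
}

#' Predicted choice probabilities for a logistic fit
#'
#' @param object A `logistic_fit` (or `rl_fit`).
#' @param design A lag-design tibble compatible with the fit.
#' @param ... Unused.
#' @return A tibble with per-trial `delta_q`, `p_heads` and `hard_call`
#'   (1 when `p_heads >= 0.5`; the tie at exactly 0.5 deterministically
#'   predicts 1).
#' @export
predict.logistic_fit <- function(object, design, ...) {
  dm <- design_matrix(design, include_rewards = object$has_alpha)
  if (ncol(dm$X) != nrow(object$coefficients)) {
    stop("design has ", ncol(dm$X) - 1, " regressors but the fit has ",
         nrow(object$coefficients) - 1, call. = FALSE)
  }
  dq <- drop(dm$X %*% object$coefficients$estimate)
  p <- plogis(dq)
  tibble::tibble(delta_q = dq, p_heads = p,
                 hard_call = as.integer(p >= 0.5))
}
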