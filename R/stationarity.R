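## Discounted-weight stationarity analysis.
##
## The logistic model is refit with exponentially discounted observation
## weights -- the sample k trials before the test trial gets weight
## (1 - eta) * eta^k -- and used for one-step-ahead prediction from the
## middle of the sequence onwards.  The discount eta that predicts best
## measures how stationary the participant's generating process is; its
## associated timescale is reported as 1 / (1 - eta).

#' Exponential discount weights
#'
#' Weight `(1 - eta) * eta^k` for the sample `k` trials before the test
#' trial, `k = 0` the most recent training trial.  Returned most-recent
#' first.  At `eta = 0` only the most recent trial has weight (the 0^0 = 1
#' convention); the weights sum to `1 - eta^n`, approaching 1.
#'
#' @param n_train Number of training trials.
#' @param eta Discount in `[0, 1)`.
#' @return Numeric vector of length `n_train`, most recent trial first.
#' @export
discount_weights <- function(n_train, eta) {
  stopifnot(n_train >= 1)
  if (length(eta) != 1 || is.na(eta) || eta < 0 || eta >= 1) {
    stop("`eta` must be in [0, 1)", call. = FALSE)
  }
  if (eta == 0) return(c(1, numeric(n_train - 1L)))
  (1 - eta) * eta^(0:(n_train - 1L))
}

#' Effective timescale of a discount parameter
#'
#' The number of trials over which discounted estimation effectively
#' averages: `1 / (1 - eta)` (so `eta = 0.998` is a 500-trial timescale);
#' `convention = "odds"` gives the alternative reading `eta / (1 - eta)`.
#'
#' @param eta Discount value(s) in `[0, 1)`.
#' @param convention `"one_minus_eta"` (default) or `"odds"`.
#' @return Timescale(s) in trials; monotone increasing in `eta`.
#' @export
effective_timescale <- function(eta, convention = c("one_minus_eta", "odds")) {
  convention <- match.arg(convention)
  stopifnot(all(eta >= 0), all(eta < 1))
  if (convention == "one_minus_eta") 1 / (1 - eta) else eta / (1 - eta)
}

#' Default discount grid
#'
#' Zero plus `n` non-zero discounts whose complements `1 - eta` are equally
#' spaced on a log scale over (10^-6, 1), so the associated timescales
#' `1 / (1 - eta)` cover ~1.7 to 10^6 trials, with several grid points at
#' the behaviourally relevant scales of hundreds of trials (eta ~ 0.998).
#'
#' @param n Number of non-zero grid values.
#' @return Increasing numeric vector of discounts in `[0, 1)`.
#' @export
eta_grid_default <- function(n = 25) {
  stopifnot(n >= 1)
  u <- seq(0, -6, length.out = n + 1)[-1]
  sort(c(0, 1 - 10^u))
}

#' Scan discount parameters for the best one-step-ahead predictor
#'
#' For each participant and each discount `eta` in the grid: starting at
#' `test_start` (default the middle trial) and stepping by `stride`, refit
#' the logistic model on all preceding trials with [discount_weights()]
#' (ridge-stabilised, since small `eta` leaves an effective sample too small
#' to identify `L + 1` coefficients) and predict the next `stride` trials
#' with the last fit; `stride = 1` is the literal per-trial protocol.  An
#' `eta` whose effective sample size `(sum w)^2 / sum w^2` stays below
#' `L + 2` is recorded as missing and excluded from the argmin.  The best
#' `eta` minimises the mean prediction error; ties go to the largest `eta`
#' (the most stationary reading).
#'
#' @param data A choice tibble (one sequence per participant; no blocks).
#' @param L Model horizon.
#' @param eta_grid Discounts to test (default [eta_grid_default()]).
#' @param stride Refit every `stride` test trials.
#' @param test_start 1-based trial at which prediction begins (default
#'   `floor(N / 2) + 1`); must be at least `L + 3`.
#' @param ridge Ridge stabiliser for the weighted fits.
#' @param timescale_convention Passed to [effective_timescale()].
#' @return A `stationarity_scan`: `curve` (tibble `participant`, `eta`,
#'   `error`, `n_test`), `best` (tibble `participant`, `eta`, `timescale`),
#'   and the scan settings.
#' @export
scan_discounting <- function(data, L, eta_grid = eta_grid_default(),
                             stride = 10, test_start = NULL, ridge = 1e-4,
                             timescale_convention = "one_minus_eta") {
  stopifnot(stride >= 1, all(eta_grid >= 0), all(eta_grid < 1))
  eta_grid <- sort(unique(eta_grid))
  data <- validate_sequences(data)
  if ("block" %in% names(data) && dplyr::n_distinct(data$block) > 1) {
    stop("the stationarity scan expects one unbroken sequence per participant",
         call. = FALSE)
  }
  parts <- split_participants(data)
  curve <- purrr::map(parts, function(d) {
    n <- nrow(d)
    start <- if (is.null(test_start)) n %/% 2 + 1L else as.integer(test_start)
    if (start < L + 3 || start > n) {
      stop("test_start must be in [L + 3, N] (participant ",
           d$participant[1], ")", call. = FALSE)
    }
    des <- build_lag_design(d, L)
    dm <- design_matrix(des)
    t_resp <- des$t
    fit_points <- seq(start, n, by = stride)
    res <- purrr::map(eta_grid, function(eta) {
      mism <- logical(0); used <- 0L; degenerate <- FALSE
      for (t0 in fit_points) {
        train <- which(t_resp < t0)
        test <- which(t_resp >= t0 & t_resp < t0 + stride)
        if (length(test) == 0) next
        w <- discount_weights(t0 - 1L, eta)[t0 - t_resp[train]]
        ## w indexed by k = t0 - 1 - t_j, i.e. position k + 1
        ess <- sum(w)^2 / sum(w^2)
        if (!is.finite(ess) || ess < L + 2) { degenerate <- TRUE; break }
        w <- w * (length(train) / sum(w))
        nf <- newton_logistic(dm$X[train, , drop = FALSE], dm$y[train],
                              w, ridge = ridge)
        p <- plogis(drop(dm$X[test, , drop = FALSE] %*% nf$beta))
        mism <- c(mism, as.integer(p >= 0.5) != dm$y[test])
        used <- used + length(test)
      }
      tibble::tibble(participant = d$participant[1], eta = eta,
                     error = if (degenerate || used == 0) NA_real_
                             else mean(mism),
                     n_test = used)
    })
    dplyr::bind_rows(res)
  })
  curve <- dplyr::bind_rows(curve)
  if (anyNA(curve$error)) {
    warning(sum(is.na(curve$error)),
            " (participant, eta) fit(s) degenerate (effective sample too ",
            "small); excluded from the argmin", call. = FALSE)
  }
  best <- dplyr::summarise(
    dplyr::group_by(curve, .data$participant),
    eta = {
      ok <- !is.na(.data$error)
      e <- .data$eta[ok][.data$error[ok] == min(.data$error[ok])]
      max(e)  # ties -> largest eta (longest timescale)
    },
    .groups = "drop")
  best$timescale <- effective_timescale(best$eta, timescale_convention)
  structure(list(curve = curve, best = best, eta_grid = eta_grid,
                 L = L, stride = stride),
            class = "stationarity_scan")
}

#' @export
print.stationarity_scan <- function(x, ...) {
  cat("Stationarity scan (L = ", x$L, ", stride = ", x$stride, ", ",
      length(x$eta_grid), " discounts)\n", sep = "")
  print(x$best, n = Inf)
  invisible(x)
}

#' @method tidy stationarity_scan
#' @export
tidy.stationarity_scan <- function(x, ...) x$curve

#' @method glance stationarity_scan
#' @export
glance.stationarity_scan <- function(x, ...) {
  tibble::tibble(n_participants = nrow(x$best),
                 median_timescale = stats::median(x$best$timescale),
                 mean_timescale = mean(x$best$timescale))
}
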