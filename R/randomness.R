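## Model-free deviation-from-randomness statistics: lagged conditional
## probabilities, the Heads-count distribution in disjoint windows of 10
## trials, the probability of alternating as a function of the preceding run
## length, and matched-size Monte-Carlo chance bands for all three.

#' Lagged conditional probabilities of repeating Heads
#'
#' Estimates \eqn{\Pr(a_t = 1 \mid a_{t-k} = 1)} for each lag `k`.  For an
#' unbiased memoryless coin every such probability is 0.5.  With
#' `by = "pooled"` counts are aggregated across participants before the
#' ratio; `by = "participant"` returns per-participant estimates (their mean
#' is the mean-of-participants variant).
#'
#' @param data A choice tibble.
#' @param lags Integer vector of lags `k >= 1`.
#' @param by `"pooled"` or `"participant"`.
#' @return A tibble `lag`, (`participant`,) `p`, `n` where `n` counts the
#'   conditioning trials; `p` is `NA` with `n = 0` when no trial conditions.
#' @export
conditional_probabilities <- function(data, lags = 1:10,
                                      by = c("pooled", "participant")) {
  by <- match.arg(by)
  stopifnot(all(lags >= 1))
  data <- validate_sequences(data)
  unit <- seq_unit_cols(data)
  pieces <- dplyr::group_split(dplyr::group_by(data,
                                               dplyr::across(dplyr::all_of(unit))))
  rows <- purrr::map(pieces, function(d) {
    a <- d$choice
    purrr::map(lags, function(k) {
      if (length(a) < k + 1) {
        return(tibble::tibble(participant = d$participant[1], lag = k,
                              hits = 0L, n = 0L))
      }
      cond <- a[seq_len(length(a) - k)] == 1L
      cur <- a[(k + 1):length(a)]
      tibble::tibble(participant = d$participant[1], lag = as.integer(k),
                     hits = sum(cur[cond] == 1L), n = sum(cond))
    })
  })
  counts <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  if (by == "pooled") {
    out <- dplyr::summarise(dplyr::group_by(counts, .data$lag),
                            hits = sum(.data$hits), n = sum(.data$n),
                            .groups = "drop")
  } else {
    out <- dplyr::summarise(dplyr::group_by(counts, .data$participant, .data$lag),
                            hits = sum(.data$hits), n = sum(.data$n),
                            .groups = "drop")
  }
  out$p <- ifelse(out$n > 0, out$hits / out$n, NA_real_)
  dplyr::select(out, -"hits")
}

#' Distribution of Heads counts in disjoint windows
#'
#' Counts Heads in disjoint consecutive windows of `window` trials (pooled
#' over participants) and normalises.  The chance reference is
#' Binomial(`window`, 0.5); human sequences are typically over-balanced,
#' with excess mass at `window / 2`.
#'
#' @param data A choice tibble (every sequence at least `window` long).
#' @param window Window length (default 10).
#' @return A tibble `heads` (0..window), `prob`, `n_windows`; `prob` sums to 1.
#' @export
heads_count_distribution <- function(data, window = 10) {
  stopifnot(window >= 1)
  data <- validate_sequences(data)
  unit <- seq_unit_cols(data)
  pieces <- dplyr::group_split(dplyr::group_by(data,
                                               dplyr::across(dplyr::all_of(unit))))
  counts <- purrr::map(pieces, function(d) {
    a <- d$choice
    if (length(a) < window) {
      stop("sequence shorter than the window (participant ",
           d$participant[1], ")", call. = FALSE)
    }
    nw <- length(a) %/% window
    as.vector(rowsum(a[seq_len(nw * window)],
                     rep(seq_len(nw), each = window)))
  })
  counts <- unlist(counts)
  tab <- tabulate(counts + 1L, nbins = window + 1L)
  tibble::tibble(heads = 0:window, prob = tab / sum(tab),
                 n_windows = as.integer(tab))
}

#' Probability of alternation by preceding run length
#'
#' For every trial `t >= 2`, the preceding run length RL is the length of
#' the maximal streak of identical symbols ending at `t - 1` (right-censored
#' at the sequence start: a streak truncated by the boundary counts at its
#' observed length).  Tallies whether the trial alternated
#' (`a_t != a_{t-1}`), aggregated by RL and pooled over participants.  For a
#' memoryless coin the alternation probability is 0.5 at every RL; the
#' gambler's fallacy predicts it rises with RL, its suppression the
#' opposite.
#'
#' @param data A choice tibble.
#' @return A tibble `run_length`, `n`, `n_alternate`, `p_alternate`; the
#'   total tally per sequence is its length minus 1.
#' @export
alternation_by_run_length <- function(data) {
  data <- validate_sequences(data)
  unit <- seq_unit_cols(data)
  pieces <- dplyr::group_split(dplyr::group_by(data,
                                               dplyr::across(dplyr::all_of(unit))))
  rows <- purrr::map(pieces, function(d) {
    a <- d$choice
    if (length(a) < 2) return(NULL)
    runs <- rle(a)$lengths
    ## within a run of length len, trials 2..len do not alternate and see
    ## RL = 1..len-1; the first trial of the next run alternates at RL = len
    no_alt <- unlist(purrr::map(runs, function(len) seq_len(len - 1L)),
                     use.names = FALSE)
    alt <- runs[-length(runs)]
    tibble::tibble(run_length = c(no_alt, alt),
                   alternate = rep(c(FALSE, TRUE), c(length(no_alt), length(alt))))
  })
  tal <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(dplyr::group_by(tal, .data$run_length),
                          n = dplyr::n(), n_alternate = sum(.data$alternate),
                          .groups = "drop")
  out$p_alternate <- out$n_alternate / out$n
  dplyr::arrange(out, .data$run_length)
}

#' Monte-Carlo chance band for a randomness statistic
#'
#' Recomputes one of the deviation-from-randomness statistics on `n_sims`
#' fair-coin datasets matched in size (`n_sequences` sequences of `n_trials`)
#' and returns the per-bin null mean and two-sided percentile band.  Used as
#' the chance reference instead of asymptotics.
#'
#' @param statistic `"conditional"`, `"heads_count"` or `"run_length"`.
#' @param n_trials,n_sequences Size of each simulated dataset (match these to
#'   the observed data).
#' @param n_sims Number of simulations (>= 100).
#' @param seed Optional integer seed.
#' @param level Band coverage (default 0.95).
#' @param lags,window Passed to the underlying statistic.
#' @param max_run_length Run-length bins above this are dropped from the band
#'   (long runs are rare under the null and their estimates unstable).
#' @return A tibble with the bin variable, `null_mean`, `lower`, `upper`.
#' @export
chance_band <- function(statistic = c("conditional", "heads_count",
                                      "run_length"),
                        n_trials, n_sequences = 1, n_sims = 1000,
                        seed = NULL, level = 0.95, lags = 1:10, window = 10,
                        max_run_length = 10) {
  statistic <- match.arg(statistic)
  stopifnot(n_sims >= 100)
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  sims <- purrr::map(seq_len(n_sims), function(i) {
    coin <- simulate_fair_coin(n_trials, n_sequences)
    switch(statistic,
      conditional = {
        cp <- conditional_probabilities(coin, lags = lags)
        tibble::tibble(bin = cp$lag, value = cp$p)
      },
      heads_count = {
        hc <- heads_count_distribution(coin, window = window)
        tibble::tibble(bin = hc$heads, value = hc$prob)
      },
      run_length = {
        rl <- alternation_by_run_length(coin)
        rl <- rl[rl$run_length <= max_run_length, ]
        tibble::tibble(bin = rl$run_length, value = rl$p_alternate)
      })
  })
  sims <- dplyr::bind_rows(sims)
  out <- dplyr::summarise(
    dplyr::group_by(sims, .data$bin),
    null_mean = mean(.data$value, na.rm = TRUE),
    lower = quantile(.data$value, probs[1], na.rm = TRUE, names = FALSE),
    upper = quantile(.data$value, probs[2], na.rm = TRUE, names = FALSE),
    n_sims = sum(!is.na(.data$value)),
    .groups = "drop")
  names(out)[1] <- switch(statistic, conditional = "lag",
                          heads_count = "heads", run_length = "run_length")
  out
}
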