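## Seedable generators: fair coins, lagged-logistic "participants",
## heterogeneous populations thereof, and two-armed operant sessions.
## These define the synthetic study conditions under which every downstream
## stage of the package is exercised and validated.

#' Simulate fair-coin sequences
#'
#' Independent equiprobable bits — the null model against which every
#' deviation-from-randomness statistic is judged.
#'
#' @param n_trials Trials per sequence.
#' @param n_sequences Number of sequences (participants).
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return A choice tibble (`participant`, `trial`, `choice`).
#' @export
simulate_fair_coin <- function(n_trials, n_sequences = 1, seed = NULL) {
  stopifnot(n_trials >= 1, n_sequences >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("coin%03d", seq_len(n_sequences))
  tibble::tibble(
    participant = rep(ids, each = n_trials),
    trial = rep(seq_len(n_trials), times = n_sequences),
    choice = as.integer(rbinom(n_trials * n_sequences, 1, 0.5))
  )
}

#' Simulate one lagged-logistic choice generator
#'
#' Runs the lagged logistic choice model generatively: after a fair-coin
#' warm-up of `L = length(beta) - 1` trials, each choice is Bernoulli with
#' \eqn{\Pr(a_t = 1) = 1 / (1 + e^{-\Delta Q_t})} and
#' \eqn{\Delta Q_t = \beta_0 + \sum_{k=1}^{L} \beta_k s_{t-k}},
#' \eqn{s = \pm 1} the signed past choices.
#'
#' @param beta Numeric vector `c(beta0, beta1, ..., betaL)`; all finite.
#' @param n_trials Number of trials (> L).
#' @param seed Optional integer seed.
#' @param participant Participant id for the returned tibble.
#' @return A choice tibble.
#' @export
simulate_logistic_agent <- function(beta, n_trials, seed = NULL,
                                    participant = "agent1") {
  if (!is.numeric(beta) || length(beta) < 1 || any(!is.finite(beta))) {
    stop("`beta` must be a finite numeric vector", call. = FALSE)
  }
  L <- length(beta) - 1L
  if (n_trials <= L) stop("`n_trials` must exceed the generator horizon L = ",
                          L, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- integer(n_trials)
  n_warm <- min(L, n_trials)
  if (n_warm > 0) a[seq_len(n_warm)] <- rbinom(n_warm, 1, 0.5)
  if (L == 0) {
    a <- rbinom(n_trials, 1, plogis(beta[1]))
  } else {
    u <- runif(n_trials)
    bl <- beta[-1]
    for (t in (L + 1L):n_trials) {
      s <- 2L * a[(t - 1L):(t - L)] - 1L
      a[t] <- as.integer(u[t] < plogis(beta[1] + sum(bl * s)))
    }
  }
  tibble::tibble(participant = participant, trial = seq_len(n_trials),
                 choice = as.integer(a))
}

#' Simulate a heterogeneous population of logistic generators
#'
#' Per-participant coefficient vectors are drawn componentwise from
#' \eqn{N(\mu_k, \sigma_k)} and each participant then generates a sequence via
#' [simulate_logistic_agent()].  The generative truth is returned so that
#' recovery can be checked downstream.
#'
#' @param n_participants,n_trials Population size and sequence length; the
#'   defaults mirror a 30-participant, 1,000-trial sequence-generation study.
#' @param beta_mean,beta_sd Numeric vectors of length `L + 1` (population mean
#'   and SD of `beta0..betaL`); `beta_sd` entries must be >= 0.
#' @param seed Optional integer seed.
#' @return A list with `data` (choice tibble) and `truth` (tibble
#'   `participant`, `term`, `value` of the drawn coefficients).
#' @export
simulate_population <- function(n_participants = 30, n_trials = 1000,
                                beta_mean, beta_sd, seed = NULL) {
  stopifnot(length(beta_mean) == length(beta_sd), all(beta_sd >= 0),
            n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n_participants))
  L1 <- length(beta_mean)
  betas <- matrix(rnorm(n_participants * L1, rep(beta_mean, each = n_participants),
                        rep(beta_sd, each = n_participants)),
                  nrow = n_participants)
  data <- purrr::map(seq_len(n_participants), function(i) {
    simulate_logistic_agent(betas[i, ], n_trials, participant = ids[i])
  })
  truth <- tibble::tibble(
    participant = rep(ids, times = L1),
    term = rep(paste0("beta", seq_len(L1) - 1L), each = n_participants),
    value = as.vector(betas)
  )
  list(data = dplyr::bind_rows(data),
       truth = dplyr::arrange(truth, .data$participant, .data$term))
}

#' Temporal-difference limit of the reward-interaction weights
#'
#' Under `alpha_k = gamma^k / temperature` (and no reward-free sequential
#' terms) the lagged value model reduces, for large `L`, to
#' temporal-difference learning with softmax choice.
#'
#' @param gamma Discount in (0, 1).
#' @param temperature Softmax temperature > 0.
#' @param L Number of lags.
#' @return Numeric vector `alpha_1..alpha_L`.
#' @export
td_alpha <- function(gamma, temperature, L) {
  stopifnot(gamma > 0, gamma < 1, temperature > 0, L >= 1)
  gamma^seq_len(L) / temperature
}

#' Simulate a two-armed operant learning session
#'
#' At each trial the linear predictor
#' \eqn{\Delta Q_t = \beta_0 + \sum_k s_{t-k}(\alpha_k r_{t-k} + \beta_k)}
#' is accumulated over the available history, the choice is Bernoulli
#' (softmax) in \eqn{\Delta Q_t}, and the chosen arm pays a Bernoulli reward
#' (arm 1 with probability `reward_probs[1]`, arm 0 with `reward_probs[2]`),
#' scaled to `reward_values`.
#'
#' @param alpha Reward-interaction weights `alpha_1..alpha_L` (e.g.
#'   [td_alpha()]); may be shorter/longer than `beta` minus one — both are
#'   zero-padded to a common horizon.
#' @param beta Reward-free weights `c(beta0, beta1, ...)`.
#' @param reward_probs Length-2 vector of win probabilities for arms 1 and 0.
#' @param n_trials Session length.
#' @param seed Optional integer seed.
#' @param participant,block Identifiers for the returned tibble.
#' @param reward_values Length-2 numeric `c(win, lose)` payoff magnitudes.
#' @return A choice tibble with columns `participant`, `block`, `trial`,
#'   `choice`, `reward`.
#' @export
simulate_operant_session <- function(alpha, beta, reward_probs,
                                     n_trials = 100, seed = NULL,
                                     participant = "agent1", block = "b01",
                                     reward_values = c(1, 0)) {
  stopifnot(n_trials >= 1, length(reward_probs) == 2,
            all(reward_probs >= 0), all(reward_probs <= 1),
            all(is.finite(alpha)), all(is.finite(beta)), length(beta) >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- max(length(alpha), length(beta) - 1L)
  al <- c(alpha, numeric(L - length(alpha)))
  bl <- c(beta[-1], numeric(L - (length(beta) - 1L)))
  b0 <- beta[1]
  a <- integer(n_trials); r <- numeric(n_trials)
  u_choice <- runif(n_trials); u_reward <- runif(n_trials)
  for (t in seq_len(n_trials)) {
    kk <- seq_len(min(L, t - 1L))
    dq <- b0
    if (length(kk) > 0) {
      s <- 2L * a[t - kk] - 1L
      dq <- dq + sum(s * (al[kk] * r[t - kk] + bl[kk]))
    }
    a[t] <- as.integer(u_choice[t] < plogis(dq))
    p_arm <- if (a[t] == 1L) reward_probs[1] else reward_probs[2]
    r[t] <- if (u_reward[t] < p_arm) reward_values[1] else reward_values[2]
  }
  tibble::tibble(participant = participant, block = block,
                 trial = seq_len(n_trials), choice = a, reward = r)
}

#' Simulate an operant-learning population
#'
#' Per-participant `alpha` and `beta` vectors are drawn componentwise normal;
#' each participant plays `n_blocks` independent sessions (histories do not
#' cross blocks) whose arm win-probabilities are drawn uniformly from
#' `reward_prob_range`, emulating blocks with differing reward schedules.
#'
#' @param n_participants,n_blocks,n_trials Population shape (default mirrors
#'   12 blocks of 100 trials).
#' @param alpha_mean,alpha_sd Length-L mean/SD for the reward-interaction
#'   weights.
#' @param beta_mean,beta_sd Length-(L+1) mean/SD for the reward-free weights.
#' @param reward_prob_range Range from which each block's two arm
#'   probabilities are drawn.
#' @param seed Optional integer seed.
#' @return A list with `data` (choice tibble with rewards and blocks) and
#'   `truth` (tibble `participant`, `term`, `value`).
#' @export
simulate_operant_population <- function(n_participants = 20, n_blocks = 12,
                                        n_trials = 100,
                                        alpha_mean, alpha_sd,
                                        beta_mean, beta_sd,
                                        reward_prob_range = c(0.1, 0.9),
                                        seed = NULL) {
  stopifnot(length(alpha_mean) == length(alpha_sd),
            length(beta_mean) == length(beta_sd),
            all(alpha_sd >= 0), all(beta_sd >= 0))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n_participants))
  La <- length(alpha_mean); Lb1 <- length(beta_mean)
  out <- vector("list", n_participants)
  truth <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    al <- rnorm(La, alpha_mean, alpha_sd)
    be <- rnorm(Lb1, beta_mean, beta_sd)
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      pr <- runif(2, reward_prob_range[1], reward_prob_range[2])
      simulate_operant_session(al, be, pr, n_trials = n_trials,
                               participant = ids[i],
                               block = sprintf("b%02d", b))
    })
    out[[i]] <- dplyr::bind_rows(blocks)
    truth[[i]] <- tibble::tibble(
      participant = ids[i],
      term = c(paste0("alpha", seq_len(La)), paste0("beta", seq_len(Lb1) - 1L)),
      value = c(al, be)
    )
  }
  list(data = dplyr::bind_rows(out), truth = dplyr::bind_rows(truth))
}

#' Exact Bayes error of a lagged-logistic generator
#'
#' The irreducible one-step prediction error of a stationary lagged-logistic
#' source, \eqn{E[\min(p, 1-p)]} under the stationary distribution of the
#' length-L history, computed exactly from the 2^L-state Markov chain of
#' histories (power iteration).
#'
#' @param beta Generator coefficients `c(beta0, ..., betaL)`.
#' @return The Bayes error, a number in `[0, 0.5]`.
#' @export
bayes_error <- function(beta) {
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  L <- length(beta) - 1L
  if (L == 0L) {
    p <- plogis(beta[1]); return(min(p, 1 - p))
  }
  n_states <- 2L^L
  codes <- 0:(n_states - 1L)
  ## bit j (0-based) of a state code holds a_{t-(j+1)}
  bits <- sapply(seq_len(L), function(k) bitwAnd(bitwShiftR(codes, k - 1L), 1L))
  bits <- matrix(bits, nrow = n_states)
  s <- 2L * bits - 1L
  p1 <- plogis(beta[1] + drop(s %*% beta[-1]))
  succ1 <- 1L + bitwShiftL(codes %% 2L^(L - 1L), 1L)  # new choice 1 -> bit0 = 1
  succ0 <- 0L + bitwShiftL(codes %% 2L^(L - 1L), 1L)
  v <- rep(1 / n_states, n_states)
  idx <- c(succ1, succ0)
  for (it in 1:5000) {
    agg <- rowsum(c(v * p1, v * (1 - p1)), idx)
    v_new <- numeric(n_states)
    v_new[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    if (max(abs(v_new - v)) < 1e-13) { v <- v_new; break }
    v <- v_new
  }
  sum(v * pmin(p1, 1 - p1))
}
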