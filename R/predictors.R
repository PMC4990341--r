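## Next-symbol predictors and their cross-validated error rates.
##
## Five models: negative recency (alternate from the last trial), balance
## (complete the minority symbol of the last L trials), lagged logistic
## regression, and two pattern nearest-neighbour models (Hamming and
## Levenshtein distance over length-L windows).  Two regimes: heterogeneous
## (per-participant parameters, contiguous 10-fold CV within participant)
## and homogeneous (one parameter set, leave-one-participant-out).
## Test-trial histories are always the participant's true preceding choices.

predictor_models <- c("negative_recency", "balance", "logistic",
                      "hamming_nn", "levenshtein")

#' Negative-recency prediction
#'
#' Predicts alternation from the previous trial: `1 - a_{t-1}`.
#'
#' @param history Integer 0/1 vector of past choices (most recent last).
#' @return A hard call, 0 or 1.
#' @export
predict_negative_recency <- function(history) {
  if (length(history) < 1) stop("empty history", call. = FALSE)
  1L - as.integer(history[length(history)])
}

#' Balance prediction
#'
#' Predicts the minority symbol of the last `L` trials (completing the local
#' Heads/Tails balance); an exact tie falls back to negative recency.
#'
#' @param history Integer 0/1 vector of past choices.
#' @param L Window length (>= 1).
#' @return A hard call, 0 or 1.
#' @export
predict_balance <- function(history, L) {
  if (length(L) != 1 || L < 1) stop("`L` must be >= 1", call. = FALSE)
  if (length(history) < L) stop("history shorter than L", call. = FALSE)
  last <- tail(history, L)
  n1 <- sum(last)
  if (n1 * 2 == L) return(predict_negative_recency(history))
  as.integer(n1 * 2 < L)
}

## Encode length-L windows: bit (k-1) of the code holds a_{t-k}.
## Returns, for a choice vector, the per-response-trial (t = L+1..N) window
## code and next symbol.
window_codes <- function(a, L) {
  m <- stats::embed(a, L + 1L)
  list(code = as.integer(m[, -1, drop = FALSE] %*% 2^(0:(L - 1L))),
       next_sym = as.integer(m[, 1]))
}

code_bits <- function(codes, L) {
  vapply(seq_len(L), function(k) bitwAnd(bitwShiftR(codes, k - 1L), 1L),
         integer(length(codes)))
}

code_string <- function(codes, L) {
  b <- matrix(code_bits(codes, L), ncol = L)
  apply(b, 1, paste, collapse = "")
}

#' Build a pattern bank of (window, next-symbol) pairs
#'
#' Extracts every (length-`L` window, next symbol) pair from the training
#' sequences and tallies next-symbol counts per distinct window -- the
#' training memory of the nearest-neighbour predictors.
#'
#' @param sequences A choice tibble, or a list of integer 0/1 vectors.
#' @param L Window length.
#' @return A tibble `code`, `n0`, `n1` with attribute `L`.
#' @export
pattern_bank <- function(sequences, L) {
  if (is.data.frame(sequences)) {
    sequences <- validate_sequences(sequences)
    unit <- seq_unit_cols(sequences)
    sequences <- purrr::map(
      dplyr::group_split(dplyr::group_by(sequences,
                                         dplyr::across(dplyr::all_of(unit)))),
      function(d) d$choice)
  }
  sequences <- purrr::keep(sequences, function(a) length(a) > L)
  if (length(sequences) == 0) stop("no training sequence longer than L",
                                   call. = FALSE)
  wc <- purrr::map(sequences, window_codes, L = L)
  code <- unlist(purrr::map(wc, "code"))
  nxt <- unlist(purrr::map(wc, "next_sym"))
  bank_from_pairs(code, nxt, L)
}

bank_from_pairs <- function(code, next_sym, L) {
  n1 <- rowsum(next_sym, code)
  n <- rowsum(rep(1L, length(code)), code)
  out <- tibble::tibble(code = as.integer(rownames(n1)),
                        n0 = as.integer(n - n1), n1 = as.integer(n1))
  attr(out, "L") <- as.integer(L)
  out
}

## Hard calls for query window codes against a bank, by minimal Hamming or
## Levenshtein distance; majority next-symbol among minimal-distance
## patterns, ties falling back to alternation from the most recent choice
## (bit 0 of the query code).
nn_calls <- function(bank, query_codes, method = c("hamming", "levenshtein")) {
  method <- match.arg(method)
  L <- attr(bank, "L")
  uq <- unique(query_codes)
  bbits <- matrix(code_bits(bank$code, L), ncol = L)
  bstr <- if (method == "levenshtein") code_string(bank$code, L)
  call_for <- vapply(uq, function(q) {
    d <- if (method == "hamming") {
      qb <- as.integer(bitwAnd(bitwShiftR(q, 0:(L - 1L)), 1L))
      rowSums(bbits != matrix(qb, nrow = nrow(bbits), ncol = L, byrow = TRUE))
    } else {
      drop(adist(code_string(q, L), bstr))
    }
    at_min <- d == min(d)
    n1 <- sum(bank$n1[at_min]); n0 <- sum(bank$n0[at_min])
    if (n1 > n0) 1L else if (n1 < n0) 0L
    else 1L - as.integer(bitwAnd(q, 1L))  # tie: alternate from a_{t-1}
  }, integer(1))
  call_for[match(query_codes, uq)]
}

#' Hamming nearest-neighbour prediction
#'
#' Among training windows at minimal Hamming distance from the last `L`
#' choices, predicts the majority next symbol; a majority tie falls back to
#' negative recency.
#'
#' @param history Integer 0/1 vector of past choices (length >= L).
#' @param bank A [pattern_bank()] (its `L` attribute sets the window).
#' @return A hard call, 0 or 1.
#' @export
predict_hamming_nn <- function(history, bank) {
  nn_call_one(history, bank, "hamming")
}

#' Levenshtein nearest-neighbour prediction
#'
#' As [predict_hamming_nn()] but with unit-cost edit distance
#' (insert/delete/substitute) between windows.
#'
#' @inheritParams predict_hamming_nn
#' @return A hard call, 0 or 1.
#' @export
predict_levenshtein <- function(history, bank) {
  nn_call_one(history, bank, "levenshtein")
}

nn_call_one <- function(history, bank, method) {
  L <- attr(bank, "L")
  if (is.null(L) || nrow(bank) == 0) stop("empty or invalid pattern bank",
                                          call. = FALSE)
  if (length(history) < L) stop("history shorter than the bank window L = ",
                                L, call. = FALSE)
  ## bit k-1 of the code holds a_{t-k}: the most recent choice is bit 0
  q <- as.integer(sum(tail(history, L) * 2^((L - 1):0)))
  nn_calls(bank, q, method)
}

## ---- cross-validated evaluation -------------------------------------------

## per-design-row hard calls for the parameter-free models
parameter_free_calls <- function(design, model, L) {
  if (model == "negative_recency") {
    as.integer(design$lag1 == -1L)
  } else {
    ssum <- rowSums(as.matrix(design[paste0("lag", seq_len(L))]))
    ifelse(ssum < 0, 1L, ifelse(ssum > 0, 0L, as.integer(design$lag1 == -1L)))
  }
}

## codes of each design row's length-L window (bit k-1 = a_{t-k})
design_codes <- function(design, L) {
  a <- (as.matrix(design[paste0("lag", seq_len(L))]) + 1L) / 2L
  as.integer(a %*% 2^(0:(L - 1L)))
}

fit_or_majority <- function(design_train) {
  tryCatch(fit_logistic_mle(design_train),
           error = function(e) list(majority = as.integer(
             mean(design_train$choice) >= 0.5)))
}

logistic_calls <- function(fit, design_test) {
  if (!is.null(fit$majority)) {
    list(call = rep(fit$majority, nrow(design_test)),
         p = rep(NA_real_, nrow(design_test)))
  } else {
    pr <- predict(fit, design_test)
    list(call = pr$hard_call, p = pr$p_heads)
  }
}

contiguous_folds <- function(n, n_folds) ceiling(seq_len(n) * n_folds / n)

#' Cross-validated prediction error, heterogeneous regime
#'
#' Fits each model separately per participant and estimates its
#' generalisation error by k-fold cross-validation over contiguous blocks of
#' trials (contiguity preserves the sequential dependence being modelled;
#' random folds are available via `fold_type`).  Parameter-free models skip
#' fitting but are evaluated on the same test trials.  Errors are averaged
#' across folds, then across participants.
#'
#' @param data A choice tibble.
#' @param model One of `"negative_recency"`, `"balance"`, `"logistic"`,
#'   `"hamming_nn"`, `"levenshtein"`.
#' @param L Model memory length.
#' @param n_folds Number of CV folds.
#' @param fold_type `"contiguous"` (default) or `"random"`.
#' @param seed Optional seed (used only for random folds).
#' @return A `predictor_result`: error rate, participant-level t-interval,
#'   per-participant errors, and per-trial predictions (with probabilities
#'   for the logistic model, for calibration).
#' @export
evaluate_heterogeneous <- function(data, model = predictor_models, L,
                                   n_folds = 10,
                                   fold_type = c("contiguous", "random"),
                                   seed = NULL) {
  model <- match.arg(model)
  fold_type <- match.arg(fold_type)
  data <- validate_sequences(data)
  if (!is.null(seed)) set.seed(seed)
  per_part <- purrr::map(split_participants(data), function(d) {
    des <- tryCatch(build_lag_design(d, L), error = function(e) NULL)
    n <- if (is.null(des)) 0L else nrow(des)
    if (n < max(n_folds, L + 2)) return(NULL)  # too short; skipped
    folds <- if (fold_type == "contiguous") contiguous_folds(n, n_folds)
             else sample(contiguous_folds(n, n_folds))
    p <- rep(NA_real_, n); call <- integer(n)
    if (model %in% c("negative_recency", "balance")) {
      call <- parameter_free_calls(des, model, L)
    } else if (model == "logistic") {
      for (f in seq_len(n_folds)) {
        test <- folds == f
        fit <- fit_or_majority(des[!test, , drop = FALSE])
        lc <- logistic_calls(fit, des[test, , drop = FALSE])
        call[test] <- lc$call; p[test] <- lc$p
      }
    } else {
      codes <- design_codes(des, L)
      method <- if (model == "hamming_nn") "hamming" else "levenshtein"
      for (f in seq_len(n_folds)) {
        test <- folds == f
        bank <- bank_from_pairs(codes[!test], des$choice[!test], L)
        call[test] <- nn_calls(bank, codes[test], method)
      }
    }
    fold_err <- tapply(call != des$choice, folds, mean)
    tibble::tibble(t = des$t, p = p, call = call, outcome = des$choice,
                   error = mean(fold_err))
  })
  predictor_result(per_part, model, "heterogeneous", L)
}

#' Cross-validated prediction error, homogeneous regime
#'
#' One parameter set for the whole population: each participant is predicted
#' by a model trained on all other participants (leave-one-participant-out;
#' stacked designs for the logistic model, pooled pattern banks for the
#' nearest-neighbour models).  Parameter-free models are unaffected by the
#' regime and are evaluated on the same test trials for comparability.
#'
#' @inheritParams evaluate_heterogeneous
#' @return A `predictor_result`.
#' @export
evaluate_homogeneous <- function(data, model = predictor_models, L) {
  model <- match.arg(model)
  data <- validate_sequences(data)
  parts <- split_participants(data)
  if (length(parts) < 2) stop("homogeneous regime needs >= 2 participants",
                              call. = FALSE)
  designs <- purrr::map(parts, function(d) {
    tryCatch(build_lag_design(d, L), error = function(e) NULL)
  })
  designs <- purrr::compact(designs)
  ids <- names(designs)
  codes <- if (model %in% c("hamming_nn", "levenshtein")) {
    purrr::map(designs, design_codes, L = L)
  }
  per_part <- purrr::map(ids, function(h) {
    des <- designs[[h]]
    p <- rep(NA_real_, nrow(des)); call <- integer(nrow(des))
    if (model %in% c("negative_recency", "balance")) {
      call <- parameter_free_calls(des, model, L)
    } else if (model == "logistic") {
      train <- dplyr::bind_rows(designs[setdiff(ids, h)])
      fit <- fit_or_majority(train)
      lc <- logistic_calls(fit, des)
      call <- lc$call; p <- lc$p
    } else {
      others <- setdiff(ids, h)
      bank <- bank_from_pairs(unlist(codes[others], use.names = FALSE),
                              unlist(purrr::map(designs[others], "choice"),
                                     use.names = FALSE), L)
      method <- if (model == "hamming_nn") "hamming" else "levenshtein"
      call <- nn_calls(bank, codes[[h]], method)
    }
    tibble::tibble(t = des$t, p = p, call = call, outcome = des$choice,
                   error = mean(call != des$choice))
  })
  names(per_part) <- ids
  predictor_result(per_part, model, "homogeneous", L)
}

predictor_result <- function(per_part, model, regime, L) {
  skipped <- names(per_part)[purrr::map_lgl(per_part, is.null)]
  if (length(skipped) > 0) {
    warning(length(skipped), " participant(s) skipped (sequence too short): ",
            paste(head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  per_part <- purrr::compact(per_part)
  if (length(per_part) == 0) stop("no participant could be evaluated",
                                  call. = FALSE)
  by_participant <- tibble::tibble(
    participant = names(per_part),
    error = purrr::map_dbl(per_part, function(x) x$error[1]),
    n_test = purrr::map_int(per_part, nrow)
  )
  preds <- dplyr::bind_rows(
    purrr::map(per_part, function(x) x[c("t", "p", "call", "outcome")]),
    .id = "participant")
  err <- mean(by_participant$error)
  n <- nrow(by_participant)
  half <- if (n > 1) stats::qt(0.975, n - 1) * sd(by_participant$error) / sqrt(n)
          else NA_real_
  structure(
    list(model = model, regime = regime, L = L, error_rate = err,
         error_ci = c(lower = err - half, upper = err + half),
         by_participant = by_participant, predictions = preds,
         skipped = skipped),
    class = "predictor_result")
}

#' @export
print.predictor_result <- function(x, ...) {
  cat("Next-symbol predictor: ", x$model, " (", x$regime, ", L = ", x$L,
      ")\n", sep = "")
  cat(sprintf("  prediction error: %.4f  [%.4f, %.4f] over %d participants\n",
              x$error_rate, x$error_ci[1], x$error_ci[2],
              nrow(x$by_participant)))
  invisible(x)
}

#' @method tidy predictor_result
#' @export
tidy.predictor_result <- function(x, ...) x$by_participant

#' @method glance predictor_result
#' @export
glance.predictor_result <- function(x, ...) {
  tibble::tibble(model = x$model, regime = x$regime, L = x$L,
                 error_rate = x$error_rate,
                 conf.low = x$error_ci[1], conf.high = x$error_ci[2],
                 n_participants = nrow(x$by_participant))
}

#' Choose the model memory length by cross-validated error
#'
#' Evaluates a model over a grid of memory lengths and returns the length
#' minimising the cross-validated error (ties go to the smallest `L`),
#' together with the full error curve.
#'
#' @inheritParams evaluate_heterogeneous
#' @param regime `"heterogeneous"` or `"homogeneous"`.
#' @param L_grid Candidate memory lengths.
#' @param ... Passed to the evaluator.
#' @return A list with `best_L` and `curve` (tibble `L`, `error`).
#' @export
select_memory_length <- function(data, model = predictor_models,
                                 regime = c("heterogeneous", "homogeneous"),
                                 L_grid, ...) {
  model <- match.arg(model)
  regime <- match.arg(regime)
  stopifnot(length(L_grid) >= 1)
  L_grid <- sort(unique(as.integer(L_grid)))
  errs <- purrr::map_dbl(L_grid, function(L) {
    res <- if (regime == "heterogeneous") {
      evaluate_heterogeneous(data, model, L, ...)
    } else {
      evaluate_homogeneous(data, model, L)
    }
    res$error_rate
  })
  list(best_L = L_grid[which.min(errs)],
       curve = tibble::tibble(L = L_grid, error = errs))
}

#' Calibration curve of predicted probabilities
#'
#' Divides predictions into `n_bins` equally populated (quantile) bins and
#' compares each bin's mean predicted probability with the empirical
#' frequency of outcome 1, plus the Pearson correlation of the two across
#' bins.  A well-calibrated predictor lies on the diagonal.
#'
#' @param predicted Predicted probabilities in (0, 1).
#' @param outcomes Realised 0/1 outcomes, same length.
#' @param n_bins Number of bins (reduced with a warning if there are fewer
#'   points than bins).
#' @return A `calibration_curve` tibble (`bin`, `n`, `predicted`,
#'   `empirical`) with attribute `r`, the Pearson correlation.
#' @export
calibration_curve <- function(predicted, outcomes, n_bins = 20) {
  stopifnot(length(predicted) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  keep <- !is.na(predicted)
  predicted <- predicted[keep]; outcomes <- outcomes[keep]
  stopifnot(all(predicted > 0), all(predicted < 1))
  if (length(predicted) < n_bins) {
    warning("fewer points than bins; reducing to ", length(predicted),
            " bins", call. = FALSE)
    n_bins <- length(predicted)
  }
  bin <- dplyr::ntile(predicted, n_bins)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin, predicted, outcomes), .data$bin),
    n = dplyr::n(),
    predicted = mean(.data$predicted),
    empirical = mean(.data$outcomes),
    .groups = "drop")
  r <- if (nrow(out) >= 2 && sd(out$predicted) > 0 && sd(out$empirical) > 0) {
    cor(out$predicted, out$empirical)
  } else NA_real_
  attr(out, "r") <- r
  class(out) <- c("calibration_curve", class(out))
  out
}
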