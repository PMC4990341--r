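## Choice-sequence tables and signed-lag design matrices.
##
## The raw unit of analysis is one participant's ordered binary choice
## sequence (optionally with per-trial rewards, and block labels for operant
## sessions).  Sequences travel as long tibbles with columns
## participant, [block,] trial, choice [, reward]; trial indices are 1-based
## in files and in the tibble, and positions within a participant x block
## unit are used internally.  Histories never cross block boundaries.

seq_unit_cols <- function(data) {
  intersect(c("participant", "block"), names(data))
}

#' Validate a choice-sequence table
#'
#' Checks the long-format schema used throughout seqfx: one row per trial,
#' columns `participant`, `trial`, `choice` (0/1), optional `reward` and
#' `block`.  Rows are returned sorted by participant, block and trial.
#'
#' @param data A data frame of choices.
#' @return The validated tibble, sorted, with `choice` as integer.
#' @export
validate_sequences <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("participant", "trial", "choice")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(data$choice %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("`choice` must be 0 or 1; first offending row: ", bad[1],
         " (choice = ", data$choice[bad[1]], ")", call. = FALSE)
  }
  if (anyNA(data$trial) || any(data$trial != as.integer(data$trial))) {
    stop("`trial` must be whole numbers", call. = FALSE)
  }
  data$participant <- as.character(data$participant)
  data$choice <- as.integer(data$choice)
  data$trial <- as.integer(data$trial)
  if ("reward" %in% names(data) && anyNA(data$reward)) {
    stop("`reward` contains missing values", call. = FALSE)
  }
  unit <- seq_unit_cols(data)
  key <- do.call(paste, c(data[unit], list(data$trial), sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (participant", if ("block" %in% unit) ", block",
         ", trial) at row ", which(duplicated(key))[1], call. = FALSE)
  }
  dplyr::arrange(data, dplyr::across(dplyr::all_of(c(unit, "trial"))))
}

#' Read choice sequences from a delimited file
#'
#' Reads a long-format choice table (`participant,trial,choice[,reward][,block]`,
#' header required).  The delimiter is auto-detected from the extension
#' (`.tsv`/`.txt` are tab, everything else comma) unless given.  Trial indices
#' are 1-based in files.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#' @return A validated tibble of choices (see [validate_sequences()]).
#' @export
read_sequences <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_sequences(data)
}

#' Write choice sequences to a delimited file
#'
#' Inverse of [read_sequences()]: a written file reads back to an identical
#' table.
#'
#' @param data A choice tibble.
#' @param path Output path; `.tsv`/`.txt` write tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(data, path) {
  data <- validate_sequences(data)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

## Signed coding of a past choice: s = a - (1 - a) in {-1, +1}.  Fixed
## package-wide so that a negative lag-1 coefficient means a propensity to
## alternate.
signed_choice <- function(a) 2L * a - 1L

#' Build a signed-lag design table
#'
#' For every participant (and block) the first `L` trials are dropped and each
#' remaining trial `t` becomes one row with response `choice` \eqn{= a_t} and
#' regressors `lag1..lagL` holding the signed past choices
#' \eqn{s_{t-k} = 2 a_{t-k} - 1 \in \{-1, +1\}}.  With `include_rewards` the
#' columns `rlag1..rlagL` hold \eqn{s_{t-k} r_{t-k}}, the reward-by-action
#' interaction regressors of the operant value model.  Lags never cross block
#' boundaries.
#'
#' @param data A choice tibble (see [validate_sequences()]).
#' @param L Positive integer model horizon (number of lags).
#' @param include_rewards Also build reward-interaction columns (requires a
#'   `reward` column).
#' @return A tibble with columns `participant`, (`block`,) `t` (1-based
#'   position of the response trial within its unit), `choice`, `lag1..lagL`
#'   (and `rlag1..rlagL`), carrying attributes `L` and `has_rewards`.
#' @export
build_lag_design <- function(data, L, include_rewards = FALSE) {
  if (length(L) != 1 || is.na(L) || L < 1 || L != as.integer(L)) {
    stop("`L` must be a positive integer", call. = FALSE)
  }
  L <- as.integer(L)
  data <- validate_sequences(data)
  if (include_rewards && !("reward" %in% names(data))) {
    stop("`include_rewards = TRUE` but no `reward` column", call. = FALSE)
  }
  unit <- seq_unit_cols(data)
  pieces <- dplyr::group_split(dplyr::group_by(data,
                                               dplyr::across(dplyr::all_of(unit))))
  out <- purrr::map(pieces, function(d) {
    n <- nrow(d)
    if (n <= L) {
      stop("sequence of length ", n, " too short for L = ", L,
           " (participant ", d$participant[1], ")", call. = FALSE)
    }
    a <- d$choice
    s <- signed_choice(a)
    t_idx <- (L + 1L):n
    cols <- list()
    for (k in seq_len(L)) cols[[paste0("lag", k)]] <- s[t_idx - k]
    if (include_rewards) {
      r <- d$reward
      for (k in seq_len(L)) cols[[paste0("rlag", k)]] <- s[t_idx - k] * r[t_idx - k]
    }
    base <- d[t_idx, c(unit), drop = FALSE]
    base$t <- t_idx
    base$choice <- a[t_idx]
    dplyr::bind_cols(base, tibble::as_tibble(cols))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "L") <- L
  attr(res, "has_rewards") <- include_rewards
  res
}

## Model matrix (intercept + signed lags [+ reward lags]) and response from a
## design tibble; shared by all fitting routines.
design_matrix <- function(design, include_rewards = FALSE) {
  L <- design_L(design)
  lag_cols <- paste0("lag", seq_len(L))
  cols <- lag_cols
  if (include_rewards) {
    rcols <- paste0("rlag", seq_len(L))
    if (!all(rcols %in% names(design))) {
      stop("design has no reward-lag columns; rebuild with include_rewards = TRUE",
           call. = FALSE)
    }
    cols <- c(cols, rcols)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(design[cols]))
  list(X = X, y = design$choice, L = L)
}

design_L <- function(design) {
  L <- attr(design, "L")
  if (is.null(L)) L <- sum(grepl("^lag[0-9]+$", names(design)))
  as.integer(L)
}
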