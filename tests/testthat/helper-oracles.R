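# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force grids, direct dynamic programming,
# and enumeration on tiny instances.

# Brute-force grid-search maximiser of the Bernoulli log-likelihood of a
# lag-1 logistic model (intercept + one signed lag).
grid_mle_lag1 <- function(s1, y, range = c(-3, 3), step = 0.01) {
  b0 <- seq(range[1], range[2], by = step)
  b1 <- seq(range[1], range[2], by = step)
  sign_flip <- ifelse(y == 1, 1, -1)  # log Pr(y) = log plogis(+/- eta)
  best <- c(NA, NA); best_ll <- -Inf
  for (b in b1) {
    eta <- outer(b0, s1 * b, `+`)  # grid rows x trials
    ll <- rowSums(plogis(sweep(eta, 2, sign_flip, `*`), log.p = TRUE))
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best <- c(b0[i], b) }
  }
  list(beta = best, loglik = best_ll)
}

# Textbook dynamic-programming edit distance (unit insert/delete/substitute).
dp_edit_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[n + 1, m + 1]
}

# Reference nearest-neighbour call: exhaustive search over every training
# (window, next) pair, with the documented tie rules.
reference_nn_call <- function(train_windows, train_next, query, dist_fun) {
  d <- vapply(train_windows, dist_fun, numeric(1), b = query)
  nxt <- train_next[d == min(d)]
  n1 <- sum(nxt == 1); n0 <- sum(nxt == 0)
  if (n1 > n0) 1L else if (n1 < n0) 0L else 1L - query[length(query)]
}

# All (window, next) pairs of a choice vector, windows oldest-to-newest.
all_window_pairs <- function(a, L) {
  idx <- (L + 1):length(a)
  list(windows = lapply(idx, function(t) a[(t - L):(t - 1)]),
       next_sym = a[idx])
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.5f within %.4g of %.5f", x, tol, target))
}
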