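# Shared fixtures, all built in code.

# the 3-subject single-covariate example: events at t = 0 and t = 2
worked_dataset <- function(x = c(5, 3, 8)) {
  survival_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                   time = c(0, 1, 2), event = c(1, 0, 1))
}

# random right-censored dataset with continuous (almost surely tie-free) times
random_dataset <- function(n, p, seed, frac_censored = 0.3) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("z", seq_len(p))))
  tt <- stats::rexp(n, 0.2 * exp(drop(Z %*% rep(0.3, p))))
  survival_dataset(Z, tt, stats::runif(n) > frac_censored)
}

# literal nested-loop survival stacking, following the per-event-time recipe
# step by step; the independent oracle for stack_exact
stack_oracle <- function(d) {
  fts <- sort(unique(d$time[d$event]))
  rows <- list()
  y <- logical(0)
  for (k in seq_along(fts)) {
    for (i in seq_along(d$time)) {
      if (d$time[i] >= fts[k]) {
        ind <- numeric(length(fts))
        ind[k] <- 1
        rows[[length(rows) + 1L]] <- c(d$covariates[i, ], ind)
        y <- c(y, d$event[i] && d$time[i] == fts[k])
      }
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- c(d$covariate_names, paste0("__risk_", seq_along(fts)))
  list(X = X, y = y)
}

# row-subset of a stacked dataset, for partitioning stacked rows into shards
stacked_subset <- function(s, idx) {
  fedcox:::new_stacked_dataset(s$X[idx, , drop = FALSE], s$y[idx],
                               s$n_covariates, s$n_indicators,
                               s$source_rows[idx], bin_times = s$bin_times)
}

# independent 1-D Breslow score function written directly from the
# partial-likelihood definition (nested sums, no shared code)
cox_score_1d <- function(b, z, times, event) {
  s <- 0
  for (i in seq_along(times)) {
    if (!event[i]) next
    at_risk <- which(times >= times[i])
    w <- exp(b * z[at_risk])
    s <- s + z[i] - sum(z[at_risk] * w) / sum(w)
  }
  s
}
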